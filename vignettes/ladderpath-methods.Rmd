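---
title: "Ladderpaths: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ladderpaths: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ladderpath)
```

## The model

A **ladderpath** describes how a target string (or a whole multiset of
strings, a *target system*) can be assembled from a user-declared **basic
set** of indivisible blocks by repeatedly concatenating blocks that are
already available.  Each *generation-operation* takes $n \ge 2$ blocks
from a partially ordered multiset, writes them together, and puts the
result back one level above its highest constituent; it costs $n-1$
**lifts**, the unit of construction length (one lift = one pairwise
concatenation).  A final special operation takes every finished target
instance out of the pot at one lift each.  Distilling a construction path
— deleting blocks whose net multiplicity is zero and taking absolute
values of the rest — yields the ladderpath: a partially ordered multiset
of **ladderons**, the blocks that were reused along the way.  Many
different paths collapse to the same ladderpath, and all of them have the
same total length, which is why the ladderpath, not the path, is the
object of interest.

Three indices summarize a target $X$:

* the **size-index** $S(X)$: the length of the shortest *trivial*
  ladderpath, i.e. the minimum number of basic blocks needed to spell all
  target instances (for single-character basic sets, the total letter
  count);
* the **ladderpath-index** $\lambda(X)$: the length of the shortest
  ladderpath — the minimal construction cost, interpretable as the
  information needed to reproduce $X$;
* the **order-index** $\omega(X) = S(X) - \lambda(X)$: the lifts saved by
  reuse, a measure of hierarchical organization.

The identity $\lambda + \omega = S$ holds by definition; the package
asserts it on every computed object.  The length of *any* ladderpath $J$
evaluates in closed form as
$$|J| \;=\; S(X) \;-\; \sum_{i \in J} m_i\,\bigl(S(i)-1\bigr),$$
the sum running over the non-basic ladderons $i$ with multiplicity $m_i$;
`ladderpath_length()` implements exactly this, and a per-unit conservation
law (every letter of the target is accounted for by
$\sum_i m_i\, n_{i,a}$ over *all* ladderons) provides an independent
structural check, `conservation_check()`.

## Search algorithms

Finding $\lambda$ is a close relative of the smallest-grammar problem and
is NP-hard, so the package offers two engines behind `ladderpath()`.

**Exact search** (`mode = "exact"`).  Targets are tokenized over the
basic set (minimum-token-count segmentation by dynamic programming) and
the engine explores *factorization states*: the set of distinct token
sequences still to be built.  A move picks a repeated subsequence of at
least two atoms with at least two pairwise disjoint occurrences, replaces
a chosen subset of those occurrences by a fresh atom, and adds the
subsequence as a new sequence to build; finalizing a state costs
$\sum(\mathrm{len}-1)$ merges.  Equal blocks created on different
branches share an atom id (atoms are registered by their flat basic-token
expansion), so states canonicalize by sorting their sequences, and the
depth-first enumeration memoizes on that canonical key.  Two admissible
lower bounds prune the search:

1. *adjacent-pair bound*: every distinct ordered pair of adjacent atoms
   in the state must be realized by at least one future merge boundary,
   and one merge realizes exactly one pair;
2. *doubling bound*: $m$ merges can assemble a block of at most $2^m$
   atoms, so the longest sequence alone needs $\lceil\log_2
   \mathrm{len}\rceil$ merges.

The second bound is what keeps highly periodic inputs (such as $A^{16}$,
where the first bound degenerates to 1) tractable.  A branch is cut as
soon as its bound cannot beat the best completion of the current node.
`optimal = TRUE` is reported only when the state space was exhausted.
The enumeration of occurrence subsets (not just maximal ones) is what
makes the search exhaustive: a repeat occurrence may be better spent as
part of a longer ladderon chosen later.

**Heuristic search** (`mode = "heuristic"`).  Repeatedly factor the
repeated subsequence of maximum expanded length (ties: more occurrences,
then lexicographically smallest string), replacing all leftmost-greedy
disjoint occurrences, then recurse — the classic longest-repeat-first
strategy.  Candidates are found by scanning window lengths upward,
stopping at the first length with no disjointly repeated window (the
disjoint occurrences of a longer repeat contain disjoint occurrences of
its prefix, so the stop is safe).  The result is flagged
`optimal = FALSE` unconditionally: it is an upper bound that in practice
is usually tight (on the bundled fixtures it matches the exact optimum
everywhere).

An independent brute-force **oracle** (`lp_oracle()`) enumerates every
subset of candidate ladderons (substrings with two disjoint occurrences)
with every combination of minimal segmentations for inputs of total
length at most 9 over at most 4 letters.  It shares no code with the
search engines; the test suite checks exact-vs-oracle agreement on
hundreds of random strings.

## Parameters that matter

* `max_exact_size` (default 40 tokens): exact search refuses larger
  inputs unless forced — an explicit guard, never a silent fallback to
  the heuristic.  40 tokens is comfortable for the exhaustive engine on
  structured strings; adversarially repetitive inputs near the limit can
  still be slow.
* `node_budget` (default 500 000 states): a hard cap on explored states.
  When it is exhausted the engine returns the heuristic decomposition
  flagged `optimal = FALSE` rather than an unverifiable partial bound.
* Tie-breaking is deterministic everywhere: tokenization prefers the
  longest block at each position among minimal segmentations; the
  validator's witness segmentation is leftmost, longest-block-first; the
  exact engine orders moves canonically (larger expanded length, more
  occurrences, then key) and returns the first optimal child.  Repeated
  runs on identical input yield the identical canonical ladderpath.  We
  do not rank all co-optimal ladderpaths lexicographically — enumerating
  the full optimal set can be exponential — so which optimum is returned
  is fixed by move order rather than by notation order.
* `seed` is accepted for interface stability but unused: both engines are
  deterministic.

## Conventions and edge cases

* Basic blocks sit at level 1; a ladderon's level is one above the
  highest level in some witness segmentation.
* The final take-out costs one lift per target instance.  Take-outs, like
  merge inputs, may drive a multiplicity negative in passing: a target
  system may remove more instances of a block than were ever explicitly
  generated, which is precisely how reuse of a replicable block is
  accounted.  Only taking out a block that was never generated (and is
  not basic) is an error.
* A target whose final multiplicity is zero is excluded from the
  partially ordered multiset but drawn (grey, with a `(0)` annotation and
  an `[×n]` count prefix) in laddergraphs.  Members of a system with
  count $c \ge 2$ surface as ladderons of multiplicity $c-1$.
* Multi-character basic sets: the size-index uses the minimum-token-count
  segmentation, and conservation is checked at the granularity of basic
  tokens (for single-character basic sets this is the per-letter law).
  Repeats are token-aligned.
* Repeats never span distinct member strings of a system: the search
  operates on a list of per-member sequences, so no separator sentinel is
  ever needed in user-visible strings.
* Degenerate inputs: an empty system has all indices 0; a target equal to
  a single basic block has $S = \lambda = 1$, $\omega = 0$.
* Text notation: levels are joined by `" // "` (the ASCII form of the
  level separator; the `⫽` glyph is accepted on input), blocks within a
  level are sorted lexicographically, `(1)` is omitted, and blocks
  containing commas, parentheses, braces, slashes, quotes or whitespace
  are double-quoted with backslash escapes.  Duplicate blocks in a
  multiset are rejected: keys are unique, so a printed multiset that
  lists the same block twice is treated as malformed input.
* Laddergraphs: edges are the constituent relations of the witness
  segmentations after transitive reduction (a block linked indirectly is
  not linked directly), and edges leaving basic blocks are dimmed.

## The synthetic generators

`random_string()` draws i.i.d. uniform letters — the incompressible foil:
for long binary strings $\omega > 0$ is guaranteed in practice (a
repeated digram always appears), while a short draw with all-distinct
letters has $\omega = 0$.  `planted_hierarchy()` builds a string by
repeated concatenation of the previous level (`reuse_factor` copies per
round), so the planted generation path is a valid witness and its length
bounds the exact $\lambda$ from above; with no accidental cross-level
repeats the bound is tight.  These generators emulate the two extremes of
the order axis — pure noise and pure hierarchy.  They do **not** emulate
natural sequences (biased composition, approximate rather than exact
repeats, long-range correlations), so passing tests demonstrate
correctness of the index algebra and search on clean compositional
structure, not performance or biological meaning on real genomic or
linguistic data.

## Problem sizes and what the checks show

The bundled fixtures are desk-scale: single strings of 16 and 34 letters,
an 18-token sequence over a 7-block basic set, and a five-member system
of 39 letters total; exact search proves optimality on all of them within
seconds (the 34-letter signal takes a few hundred states).  The
randomized exact-vs-oracle suite runs 500 strings of length at most 9
over alphabets of at most 4 letters, plus structural property checks on
every result.  The long-string heuristic demonstration uses a
1000-letter binary draw.

One fixture deserves a remark: for the 18-token sequence `Yprime` the
package's exhaustive search proves $\lambda = 15$, one lift below the
16-lift reference decomposition recorded in `lp_fixtures()` (built on the
ladderon `TEF`).  The shorter ladderpath uses `EFHK`, whose two disjoint
occurrences save two lifts where the overlapping `TEF` can save only one;
the 16-lift multiset is still a valid ladderpath and evaluates to 16
under the length formula.  The package reports the computed optimum.

## Known limitations

* Exact search is exponential in the worst case (the problem is at least
  as hard as an NP-complete problem); the guard and budget make the
  failure mode explicit rather than absent.
* The heuristic carries no approximation guarantee.
* The oracle is deliberately restricted to tiny inputs and
  single-character basic sets.
* Laddergraph export emits DOT text only; rendering is left to Graphviz.
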