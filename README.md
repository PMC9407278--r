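# ladderpath

Hierarchical decomposition of strings into reused building blocks, and
the complexity indices that come with it.

## The problem

How cheaply can a target string — or a whole multiset of strings — be
assembled from a declared alphabet of indivisible blocks, if anything
built once can be reused for free?  Each pairwise concatenation costs one
*lift*; taking a finished target instance out costs one lift.  The
shortest such construction defines the **ladderpath-index**
λ(X), the minimal cost (and, in the assembly-theory sense, the
information needed) to reproduce X.  Against it stand the **size-index**
S(X) — the cost of building X naively from basic blocks, i.e. the length
of the shortest *trivial* ladderpath — and the **order-index**

ω(X) = S(X) − λ(X),

the lifts saved by reuse, a measure of how hierarchically organized X is.
The identity λ + ω ≡ S always holds.  The decomposition itself is a
*ladderpath*: a partially ordered multiset of reused blocks
(*ladderons*), e.g. for X = `ABCDBCDBCDCDEFEF`

```
{A, B, C, D, E, F // CD, EF // BCD(2)}
```

where `//` separates levels and `BCD(2)` is a ladderon reused with
multiplicity 2.  Any ladderpath J evaluates in closed form as
|J| = S(X) − Σᵢ mᵢ·(S(i) − 1) over its non-basic ladderons.

The package is aimed at researchers quantifying compositional complexity
and reuse — in origin-of-life models, sequence analysis, language or
technology evolution — who need exact desk-scale computations, validated
user-supplied decompositions, and reproducible reports.  Finding λ is a
close relative of the smallest-grammar problem (NP-hard), so the package
pairs an exhaustive branch-and-bound engine for small inputs with a
longest-repeat-first heuristic for everything else, plus an independent
brute-force oracle used by the test suite.

## A worked example

```r
library(ladderpath)
fit <- ladderpath("ABCDBCDBCDCDEFEF")   # exact search, single-letter basic set
print(fit)
#> Ladderpath of 1 target instance(s), 1 distinct string(s)
#>   {A, B, C, D, E, F // CD, EF // BCD(2)}
#>   S = 16, lambda = 10, omega = 6 lifts
#>   search: exact (proven shortest)
summary(fit)
#> Ladderpath summary
#>   notation: {A, B, C, D, E, F // CD, EF // BCD(2)}
#>   size-index S      =  16 lifts
#>   ladderpath-index  =  10 lifts (lambda)
#>   order-index       =   6 lifts (omega)
#>   non-basic ladderons:
#>     CD           level 2, multiplicity 1, saves 1 lift(s)
#>     EF           level 2, multiplicity 1, saves 1 lift(s)
#>     BCD          level 3, multiplicity 2, saves 4 lift(s)
```

The 16-letter string costs 16 lifts naively; building `CD`, `EF` and
`BCD` once each and reusing `BCD` twice more brings the optimal cost to
10 lifts, so 6 lifts of structure are "stored" in the reuse hierarchy.
`coef(fit)` returns the triple, `plot(fit)` draws the laddergraph, and
`export_laddergraph(fit, "x.dot")` writes Graphviz DOT with levels
ranked, basic edges dimmed and transitively redundant edges removed.

Other entry points follow the same grammar: `target_system()` for
multisets with counts, `basic_set()` for custom (also multi-character)
alphabets, `parse_pom()` / `serialize_pom()` for the text notation,
`validate_ladderpath()` for checking a user-supplied multiset (with a
replayable witness generation path), `simulate_path()` /
`path_to_ladderpath()` for the procedural view, and `lp_oracle()` for
tiny exhaustive cross-checks.

A command-line tool wraps it all:

```sh
exec/ladderpath compute --mode exact --targets X.txt --out json
exec/ladderpath validate --pom jx2.pom --targets X.txt
```

with `--basic-set`, `--format lines|fasta`, `--out json|tsv|pom`,
`--graph FILE.dot`, `--max-exact-size`, `--node-budget` and `--verbose`.

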