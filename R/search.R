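#' Search control parameters
#'
#' @param max_exact_size refuse exact search when the total token count of
#'   the distinct target strings exceeds this (unless `force = TRUE` in
#'   [ladderpath()]); the heuristic has no size guard.
#' @param node_budget cap on the number of factorization states the exact
#'   search may explore; when exceeded the result is flagged
#'   `optimal = FALSE`.
#' @param tie_break canonical ordering id for deterministic tie-breaking
#'   (only `"canonical"` is implemented).
#' @param seed reserved; both searches are deterministic.
#' @return A list of class `lp_control`.
#' @export
lp_control <- function(max_exact_size = 40L, node_budget = 500000L,
                       tie_break = "canonical", seed = NULL) {
  stopifnot(max_exact_size >= 1L, node_budget >= 1L)
  structure(list(max_exact_size = as.integer(max_exact_size),
                 node_budget = as.integer(node_budget),
                 tie_break = tie_break, seed = seed),
            class = "lp_control")
}

## ---- shared machinery ---------------------------------------------------
## The search works on token sequences: every distinct target string is
## tokenized over the basic set, and factoring a repeated subsequence with
## k >= 2 disjoint occurrences replaces the occurrences by a fresh atom and
## adds the subsequence as a new sequence to build.  The ladderpath length
## is (merges needed) + (number of target instances); finalizing a state
## costs sum(len - 1) merges.  Atoms are registered globally by their
## basic-token expansion, so equal blocks created on different branches
## share an id and states canonicalize by sorting their sequences.

lp_search_env <- function(basic, target) {
  nb <- length(basic$blocks)
  e <- new.env(parent = emptyenv())
  e$basic <- basic
  e$target <- target
  e$expansions <- as.list(seq_len(nb))      # atom id -> basic-token vector
  e$reg <- new.env(parent = emptyenv())     # expansion key -> atom id
  for (i in seq_len(nb)) e$reg[[as.character(i)]] <- i
  e$nodes <- 0L
  e$complete <- TRUE
  e
}

## register the atom whose content is the concatenation of the atoms in
## `sub`; atoms are keyed by their flat basic-token expansion, so equal
## blocks reached along different branches share one id
lp_atom <- function(e, sub) {
  basexp <- unlist(e$expansions[sub], use.names = FALSE)
  key <- paste(basexp, collapse = ",")
  id <- e$reg[[key]]
  if (!is.null(id)) return(id)
  id <- length(e$expansions) + 1L
  e$expansions[[id]] <- basexp
  e$reg[[key]] <- id
  id
}

lp_atom_expansion <- function(e, id) e$expansions[[id]]

lp_atom_string <- function(e, id) {
  paste(e$basic$blocks[e$expansions[[id]]], collapse = "")
}

lp_state_key <- function(state) {
  paste(sort(vapply(state, paste, "", collapse = ",")), collapse = ";")
}

lp_finalize_cost <- function(state) {
  if (length(state) == 0L) return(0L)
  sum(lengths(state)) - length(state)
}

## admissible lower bound on the merges still needed, the larger of two
## arguments: (i) every distinct ordered pair of adjacent atoms present in
## the state must be realized by at least one future merge boundary, and
## one merge realizes exactly one such pair; (ii) m merges can assemble a
## block of at most 2^m atoms (each merge at most doubles the longest
## constructible block), so the longest sequence alone needs
## ceil(log2(len)) merges
lp_digram_bound <- function(state) {
  pairs <- character(0)
  maxlen <- 1L
  for (s in state) {
    if (length(s) < 2L) next
    if (length(s) > maxlen) maxlen <- length(s)
    pairs <- c(pairs, paste(s[-length(s)], s[-1]))
  }
  max(length(unique(pairs)), as.integer(ceiling(log2(maxlen))))
}

## all repeated contiguous subsequences (>= 2 atoms) with their occurrences
## (si = sequence index, i..j = atom span); only groups admitting >= 2
## pairwise-disjoint occurrences are returned, sorted deterministically
lp_repeat_groups <- function(e, state) {
  keys <- character(0); si_ <- integer(0); i_ <- integer(0); j_ <- integer(0)
  for (si in seq_along(state)) {
    s <- state[[si]]
    L <- length(s)
    if (L < 2L) next
    for (i in 1:(L - 1L)) {
      acc <- as.character(s[i])
      for (j in (i + 1L):L) {
        acc <- paste0(acc, ",", s[j])
        keys <- c(keys, acc); si_ <- c(si_, si); i_ <- c(i_, i); j_ <- c(j_, j)
      }
    }
  }
  if (!length(keys)) return(list())
  grp <- split(seq_along(keys), keys)
  grp <- grp[lengths(grp) >= 2L]
  out <- list()
  for (key in names(grp)) {
    idx <- grp[[key]]
    occ <- data.frame(si = si_[idx], i = i_[idx], j = j_[idx])
    occ <- occ[order(occ$si, occ$i), , drop = FALSE]
    # at least two pairwise disjoint occurrences?
    ok <- FALSE
    last_end <- -1L; last_si <- -1L; taken <- 0L
    for (r in seq_len(nrow(occ))) {
      if (occ$si[r] != last_si || occ$i[r] > last_end) {
        taken <- taken + 1L; last_si <- occ$si[r]; last_end <- occ$j[r]
      }
      if (taken >= 2L) { ok <- TRUE; break }
    }
    if (!ok) next
    sub <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
    explen <- sum(lengths(e$expansions[sub]))
    out[[length(out) + 1L]] <- list(sub = sub, occ = occ, key = key,
                                    explen = explen)
  }
  if (!length(out)) return(out)
  # deterministic order: larger expanded length first, then more
  # occurrences, then key
  ord <- order(-vapply(out, `[[`, 0L, "explen"),
               -vapply(out, function(g) nrow(g$occ), 0L),
               vapply(out, `[[`, "", "key"), method = "radix")
  out[ord]
}

## all subsets (size >= 2) of pairwise-disjoint occurrences, in
## deterministic DFS order
lp_disjoint_subsets <- function(occ) {
  n <- nrow(occ)
  res <- list()
  rec <- function(r, chosen) {
    if (r > n) {
      if (length(chosen) >= 2L) res[[length(res) + 1L]] <<- chosen
      return(invisible())
    }
    # include occ r if disjoint from all chosen
    ok <- TRUE
    for (c0 in chosen) {
      if (occ$si[c0] == occ$si[r] &&
          !(occ$i[r] > occ$j[c0] || occ$j[r] < occ$i[c0])) { ok <- FALSE; break }
    }
    if (ok) rec(r + 1L, c(chosen, r))
    rec(r + 1L, chosen)
  }
  rec(1L, integer(0))
  res
}

## apply one factoring move; returns the child state (unique sequences,
## single-atom sequences dropped)
lp_apply_move <- function(e, state, sub, occ, subset) {
  t <- lp_atom(e, sub)
  occ <- occ[subset, , drop = FALSE]
  for (si in unique(occ$si)) {
    rows <- occ[occ$si == si, , drop = FALSE]
    rows <- rows[order(-rows$i), , drop = FALSE]  # replace right to left
    s <- state[[si]]
    for (r in seq_len(nrow(rows))) {
      s <- c(if (rows$i[r] > 1L) s[1:(rows$i[r] - 1L)] else integer(0),
             t,
             if (rows$j[r] < length(s)) s[(rows$j[r] + 1L):length(s)]
             else integer(0))
    }
    state[[si]] <- s
  }
  state[[length(state) + 1L]] <- sub
  state <- state[lengths(state) >= 2L]
  keys <- vapply(state, paste, "", collapse = ",")
  state[!duplicated(keys)]
}

## ---- exact search -------------------------------------------------------
## Depth-first enumeration over factorization states with memoization on
## the canonical state and branch-and-bound pruning by the digram lower
## bound.  Returns the exact minimum number of merges for the state (when
## the node budget holds).
lp_solve_exact <- function(e, state, memo, budget) {
  if (length(state) == 0L) return(0L)
  key <- lp_state_key(state)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  fin <- lp_finalize_cost(state)
  if (e$nodes >= budget) { e$complete <- FALSE; return(fin) }
  e$nodes <- e$nodes + 1L
  lb <- lp_digram_bound(state)
  if (lb >= fin) { memo[[key]] <- fin; return(fin) }
  best <- fin
  groups <- lp_repeat_groups(e, state)
  for (g in groups) {
    for (subset in lp_disjoint_subsets(g$occ)) {
      child <- lp_apply_move(e, state, g$sub, g$occ, subset)
      if (lp_digram_bound(child) >= best) next
      v <- lp_solve_exact(e, child, memo, budget)
      if (v < best) best <- v
      if (best <= lb) break  # cannot go below the lower bound
    }
    if (best <= lb) break
  }
  if (e$complete) memo[[key]] <- best
  best
}

## replay the optimal decisions to recover the final productions
lp_walk_exact <- function(e, state, memo, budget) {
  repeat {
    v <- lp_solve_exact(e, state, memo, budget)
    if (v == lp_finalize_cost(state)) return(state)
    found <- FALSE
    for (g in lp_repeat_groups(e, state)) {
      for (subset in lp_disjoint_subsets(g$occ)) {
        child <- lp_apply_move(e, state, g$sub, g$occ, subset)
        if (lp_solve_exact(e, child, memo, budget) == v) {
          state <- child; found <- TRUE; break
        }
      }
      if (found) break
    }
    if (!found) return(state)  # defensive; cannot happen when complete
  }
}

## candidate repeats for the heuristic: scan window lengths upward and stop
## at the first length with no disjointly-repeated window (the two disjoint
## occurrences of a longer repeat contain disjoint occurrences of its
## prefix, so no longer repeat can exist either); avoids the O(n^2)
## all-subsequence enumeration on long inputs
lp_heur_groups <- function(e, state) {
  out <- list()
  L <- 2L
  repeat {
    keys <- character(0); si_ <- integer(0); i_ <- integer(0)
    for (si in seq_along(state)) {
      s <- state[[si]]
      n <- length(s) - L + 1L
      if (n < 1L) next
      w <- vapply(seq_len(n), function(i)
        paste(s[i:(i + L - 1L)], collapse = ","), "")
      keys <- c(keys, w); si_ <- c(si_, rep.int(si, n))
      i_ <- c(i_, seq_len(n))
    }
    if (!length(keys)) break
    grp <- split(seq_along(keys), keys)
    grp <- grp[lengths(grp) >= 2L]
    found <- FALSE
    for (key in names(grp)) {
      idx <- grp[[key]]
      occ <- data.frame(si = si_[idx], i = i_[idx], j = i_[idx] + L - 1L)
      occ <- occ[order(occ$si, occ$i), , drop = FALSE]
      taken <- 0L; last_si <- -1L; last_end <- -1L
      for (r in seq_len(nrow(occ))) {
        if (occ$si[r] != last_si || occ$i[r] > last_end) {
          taken <- taken + 1L; last_si <- occ$si[r]; last_end <- occ$j[r]
        }
        if (taken >= 2L) break
      }
      if (taken < 2L) next
      found <- TRUE
      sub <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
      out[[length(out) + 1L]] <-
        list(sub = sub, occ = occ, key = key,
             explen = sum(lengths(e$expansions[sub])))
    }
    if (!found) break
    L <- L + 1L
  }
  out
}

## ---- heuristic search ---------------------------------------------------
## Longest-repeat-first: repeatedly factor the repeated subsequence of
## maximum expanded length (ties: more occurrences, then lexicographically
## smallest expansion), replacing all leftmost-greedy disjoint occurrences.
lp_solve_heuristic <- function(e, state) {
  repeat {
    groups <- lp_heur_groups(e, state)
    if (!length(groups)) return(state)
    best <- NULL
    for (g in groups) {
      g$string <- paste(e$basic$blocks[unlist(e$expansions[g$sub])],
                        collapse = "")
      # leftmost-greedy disjoint occurrence selection
      sel <- integer(0); last_si <- -1L; last_end <- -1L
      for (r in seq_len(nrow(g$occ))) {
        if (g$occ$si[r] != last_si || g$occ$i[r] > last_end) {
          sel <- c(sel, r); last_si <- g$occ$si[r]; last_end <- g$occ$j[r]
        }
      }
      g$sel <- sel
      if (is.null(best) ||
          g$explen > best$explen ||
          (g$explen == best$explen && length(g$sel) > length(best$sel)) ||
          (g$explen == best$explen && length(g$sel) == length(best$sel) &&
           g$string < best$string))
        best <- g
    }
    state <- lp_apply_move(e, state, best$sub, best$occ, best$sel)
  }
}

## ---- assembling the result ----------------------------------------------
## Final productions (one token sequence per distinct built block) ->
## ladderon table with multiplicities and levels, by multiset bookkeeping:
## every composite owner is created once, consumed per use and per
## take-out; surviving nonzero balances are the ladderons.
lp_build_result <- function(e, prods) {
  basic <- e$basic; target <- e$target
  owner <- vapply(prods, function(s)
    paste(basic$blocks[unlist(e$expansions[s], use.names = FALSE)],
          collapse = ""), "")
  atom_ids <- sort(unique(c(unlist(prods),
                            seq_along(basic$blocks))))
  atom_str <- vapply(atom_ids, function(a) lp_atom_string(e, a), "")
  blocks <- unique(c(atom_str, owner))
  uses <- structure(rep.int(0L, length(blocks)), names = blocks)
  for (s in prods) {
    st <- atom_str[match(s, atom_ids)]
    for (b in st) uses[b] <- uses[b] + 1L
  }
  takeout <- structure(rep.int(0L, length(blocks)), names = blocks)
  for (i in seq_len(nrow(target))) {
    s <- target$string[i]
    if (!s %in% blocks) {  # member equal to no atom/owner: single-token member
      blocks <- c(blocks, s)
      uses <- c(uses, structure(0L, names = s))
      takeout <- c(takeout, structure(0L, names = s))
    }
    takeout[s] <- takeout[s] + target$count[i]
  }
  is_basic <- blocks %in% basic$blocks
  created <- as.integer(blocks %in% owner)
  net <- created - uses[blocks] - takeout[blocks]
  # levels, bottom-up by expanded length
  level <- structure(rep.int(1L, length(blocks)), names = blocks)
  prod_of <- structure(vector("list", length(blocks)), names = blocks)
  for (k in seq_along(prods)) prod_of[[owner[k]]] <- prods[[k]]
  for (b in blocks[order(nchar(blocks), method = "radix")]) {
    p <- prod_of[[b]]
    if (is.null(p)) next
    level[b] <- 1L + max(level[atom_str[match(p, atom_ids)]])
  }
  keep <- net != 0L
  ladderons <- data.frame(block = blocks[keep],
                          multiplicity = abs(as.integer(net[keep])),
                          level = as.integer(level[keep]),
                          stringsAsFactors = FALSE)
  ladderons
}

#' Compute a shortest (or short) ladderpath of a target system
#'
#' The central fitting function.  The target strings are tokenized over the
#' basic set and decomposed hierarchically into reused ladderons.  In
#' `"exact"` mode a depth-first branch-and-bound search over all
#' deterministic factorization schemes (with memoization on canonicalized
#' states and an admissible adjacent-pair lower bound) returns a ladderpath
#' of globally minimum length; in `"heuristic"` mode repeated substrings of
#' maximum length are factored greedily, which is fast and usually short
#' but carries no optimality guarantee.
#'
#' @param target a [target_system()], or a character vector of target
#'   strings (duplicates accumulate multiplicity).
#' @param basic a [basic_set()]; defaults to the single characters observed
#'   in the target.
#' @param mode `"exact"` or `"heuristic"`.
#' @param control a [lp_control()] object.
#' @param force run exact search even past `max_exact_size`.
#' @return An object of class `ladderpath` with components `ladderons`
#'   (block / multiplicity / level), the indices `S`, `lambda`, `omega`
#'   (all in lifts), and `optimal` (`TRUE` only when the exact state space
#'   was exhausted).
#' @examples
#' fit <- ladderpath("ABCDBCDBCDCDEFEF")
#' coef(fit)          # S = 16, lambda = 10, omega = 6
#' @export
ladderpath <- function(target, basic = NULL, mode = c("exact", "heuristic"),
                       control = lp_control(), force = FALSE) {
  mode <- match.arg(mode)
  cl <- match.call()
  target <- as_target_system(target)
  if (nrow(target) == 0L) {
    basic <- if (is.null(basic)) basic_set("?") else basic
    lp <- new_ladderpath(data.frame(), basic, target, mode = mode,
                         optimal = TRUE, call = cl)
    return(lp)
  }
  if (is.null(basic)) basic <- default_basic_set(target$string)
  toks <- lapply(target$string, lp_tokenize, basic = basic)
  total_tokens <- sum(lengths(toks))
  if (mode == "exact" && total_tokens > control$max_exact_size && !force)
    stop(sprintf(paste0("exact search refused: %d tokens exceed ",
                        "max_exact_size = %d; use mode = \"heuristic\" or ",
                        "force = TRUE"),
                 total_tokens, control$max_exact_size), call. = FALSE)
  e <- lp_search_env(basic, target)
  state <- toks[lengths(toks) >= 2L]
  keys <- vapply(state, paste, "", collapse = ",")
  state <- state[!duplicated(keys)]
  if (mode == "exact") {
    memo <- new.env(parent = emptyenv())
    lp_solve_exact(e, state, memo, control$node_budget)
    if (e$complete) {
      prods <- lp_walk_exact(e, state, memo, control$node_budget)
      optimal <- TRUE
    } else {
      # budget exhausted: fall back to the best constructive decomposition
      prods <- lp_solve_heuristic(e, state)
      optimal <- FALSE
    }
  } else {
    prods <- lp_solve_heuristic(e, state)
    optimal <- FALSE
  }
  ladderons <- lp_build_result(e, prods)
  lp <- new_ladderpath(ladderons, basic, target, mode = mode,
                       optimal = optimal, call = cl)
  lp$nodes_explored <- e$nodes
  lp
}
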