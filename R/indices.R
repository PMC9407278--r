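#' Size-index of a target (or single block) over a basic set
#'
#' The size-index S is the length, in lifts, of the shortest trivial
#' ladderpath: the minimum number of basic blocks needed to spell every
#' target instance.  With single-character basic blocks this is simply the
#' total letter count; with multi-character blocks each distinct member is
#' segmented by dynamic programming into the fewest blocks, and counts
#' multiply.
#'
#' @param target an [target_system()], or a character vector coerced to one.
#' @param basic a [basic_set()]; defaults to the single characters observed
#'   in the target.
#' @return Integer number of lifts.
#' @examples
#' size_index("ABCDBCDBCDCDEFEF")                       # 16
#' size_index("ABCDBCDBCDCDEFEF",
#'            basic_set(c(LETTERS[1:6], "BCD")))        # 10
#' @export
size_index <- function(target, basic = NULL) {
  target <- as_target_system(target)
  if (nrow(target) == 0L) return(0L)
  if (is.null(basic)) basic <- default_basic_set(target$string)
  per <- vapply(target$string, lp_min_tokens, 1L, basic = basic)
  sum(as.integer(per) * target$count)
}

## per-ladderon size-indices for a ladderpath object
lp_block_sizes <- function(lp) {
  vapply(lp$ladderons$block, lp_min_tokens, 1L, basic = lp$basic)
}

#' Length of a ladderpath from its partially ordered multiset
#'
#' Evaluates the closed-form length: the target's size-index minus the lifts
#' saved by reuse, `S(target) - sum_i m_i * (S_i - 1)` over the non-basic
#' ladderons `i` with multiplicity `m_i` and size-index `S_i`.  Basic-block
#' ladderons contribute nothing.
#'
#' @param lp a `ladderpath` object (from [ladderpath()], [parse_pom()] or
#'   [path_to_ladderpath()]).
#' @return Integer length in lifts.
#' @export
ladderpath_length <- function(lp) {
  stopifnot(inherits(lp, "ladderpath"))
  S <- size_index(lp$target, lp$basic)
  if (nrow(lp$ladderons) == 0L) return(S)
  nb <- !lp$ladderons$basic
  if (!any(nb)) return(S)
  sizes <- vapply(lp$ladderons$block[nb], lp_min_tokens, 1L, basic = lp$basic)
  S - sum(lp$ladderons$multiplicity[nb] * (sizes - 1L))
}

#' Order-index of a ladderpath
#'
#' The lifts saved by reuse: `sum_i m_i * (S_i - 1)` over the non-basic
#' ladderons.  Identically equal to `size_index(target) -
#' ladderpath_length(lp)`.
#'
#' @inheritParams ladderpath_length
#' @return Integer number of lifts (>= 0 for any valid ladderpath).
#' @export
order_index <- function(lp) {
  stopifnot(inherits(lp, "ladderpath"))
  if (nrow(lp$ladderons) == 0L) return(0L)
  nb <- !lp$ladderons$basic
  if (!any(nb)) return(0L)
  sizes <- vapply(lp$ladderons$block[nb], lp_min_tokens, 1L, basic = lp$basic)
  sum(lp$ladderons$multiplicity[nb] * (sizes - 1L))
}

#' Per-unit conservation report for a ladderpath
#'
#' For every letter `a` (or, with a multi-character basic set, every basic
#' block token) the total count over all target instances must equal
#' `sum_i m_i * n_ia` over *all* ladderons, where `n_ia` counts the unit in
#' ladderon `i`.  Any valid ladderpath passes for every unit.
#'
#' @inheritParams ladderpath_length
#' @return A data frame with columns `unit`, `target_count`,
#'   `ladderon_count` and `ok`.
#' @export
conservation_check <- function(lp) {
  stopifnot(inherits(lp, "ladderpath"))
  basic <- lp$basic
  units <- basic$blocks
  count_units <- function(s) {
    toks <- lp_tokenize(s, basic, what = s)
    tabulate(toks, nbins = length(units))
  }
  lhs <- rep.int(0L, length(units))
  for (i in seq_len(nrow(lp$target)))
    lhs <- lhs + count_units(lp$target$string[i]) * lp$target$count[i]
  rhs <- rep.int(0L, length(units))
  for (i in seq_len(nrow(lp$ladderons)))
    rhs <- rhs + count_units(lp$ladderons$block[i]) * lp$ladderons$multiplicity[i]
  data.frame(unit = units, target_count = lhs, ladderon_count = rhs,
             ok = lhs == rhs, stringsAsFactors = FALSE)
}
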