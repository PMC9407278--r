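#' Worked-example fixtures
#'
#' The five standard worked examples used throughout the documentation and
#' tests: a structured single string `X`, a same-length random-looking
#' string `W`, a five-member target system `Q`, a 34-letter signal `Y`, and
#' `Y'` -- the same signal read over a coarser, multi-character basic set
#' `{T, R, H, K, EF, MU, BCD}`.  Each fixture carries its target, basic
#' set, and expected index triple (S, lambda, omega).
#'
#' @return A named list of fixtures, each a list with elements `target`,
#'   `basic` and `expected` (named integer vector `S`, `lambda`, `omega`).
#' @export
lp_fixtures <- function() {
  list(
    X = list(target = target_system("ABCDBCDBCDCDEFEF"),
             basic = basic_set(LETTERS[1:6]),
             expected = c(S = 16L, lambda = 10L, omega = 6L)),
    W = list(target = target_system("ABCDEFCFEDCBFDBA"),
             basic = basic_set(LETTERS[1:6]),
             expected = c(S = 16L, lambda = 16L, omega = 0L)),
    Q = list(target = target_system(
               c("ABDEDBED", "ABDED", "ABDABD", "CAB", "ED"),
               counts = c(2L, 1L, 1L, 2L, 3L)),
             basic = basic_set(LETTERS[1:5]),
             expected = c(S = 39L, lambda = 17L, omega = 22L)),
    Y = list(target = target_system("TBCDEFRBCDEFTEFHKREFHJKLMUVTEFPSMU"),
             basic = basic_set(c("B", "C", "D", "E", "F", "H", "J", "K",
                                 "L", "M", "P", "R", "S", "T", "U", "V")),
             expected = c(S = 34L, lambda = 25L, omega = 9L)),
    Yprime = list(target = target_system("TBCDEFRBCDEFTEFHKREFHKMUTEFMU"),
                  basic = basic_set(c("T", "R", "H", "K", "EF", "MU",
                                      "BCD")),
                  expected = c(S = 18L, lambda = 16L, omega = 2L))
  )
}

#' Replayable example generation paths
#'
#' Four hand-written generation paths for the fixtures: three alternative
#' constructions of the string `X` (lengths 10, 13 and 13 lifts; the second
#' and third distill to the same ladderpath) and one construction of the
#' target system `Q` (length 17 lifts).
#'
#' @return A named list of [generation_path()] objects.
#' @export
lp_example_paths <- function() {
  bX <- basic_set(LETTERS[1:6])
  tX <- target_system("ABCDBCDBCDCDEFEF")
  ex1 <- generation_path(list(
    op_merge(c("C", "D")),
    op_merge(c("B", "CD")),
    op_merge(c("E", "F")),
    op_merge(c("A", "BCD", "BCD", "BCD", "CD", "EF", "EF")),
    op_takeout("ABCDBCDBCDCDEFEF")), bX, tX)
  ex2 <- generation_path(list(
    op_merge(c("D", "B", "C")),
    op_merge(c("E", "F")),
    op_merge(c("A", "B", "C")),
    op_merge(c("DBC", "DBC")),
    op_merge(c("C", "D")),
    op_merge(c("ABC", "DBCDBC", "D", "CD", "EF", "EF")),
    op_takeout("ABCDBCDBCDCDEFEF")), bX, tX)
  ex3 <- generation_path(list(
    op_merge(c("D", "B", "C")),
    op_merge(c("E", "F")),
    op_merge(c("A", "B", "C", "DBC", "DBC", "D", "C", "D", "EF", "EF")),
    op_takeout("ABCDBCDBCDCDEFEF")), bX, tX)
  bQ <- basic_set(LETTERS[1:5])
  tQ <- target_system(c("ABDEDBED", "ABDED", "ABDABD", "CAB", "ED"),
                      counts = c(2L, 1L, 1L, 2L, 3L))
  ex4 <- generation_path(list(
    op_merge(c("A", "B")),
    op_merge(c("C", "AB")),
    op_merge(c("AB", "D")),
    op_merge(c("ABD", "ABD")),
    op_merge(c("E", "D")),
    op_merge(c("ABD", "ED")),
    op_merge(c("ABDED", "B", "ED")),
    op_takeout(c("ABDEDBED", "ABDEDBED", "ABDED", "ABDABD",
                 "CAB", "CAB", "ED", "ED", "ED"))), bQ, tQ)
  list(Ex1 = ex1, Ex2 = ex2, Ex3 = ex3, Ex4 = ex4)
}

#' Random target strings
#'
#' Draws `n` i.i.d. uniform letters from an alphabet of `k` symbols -- the
#' "totally random sequence" foil against which ordered strings are
#' compared.  Reproducible under `seed`; the global random-number state is
#' left untouched.
#'
#' @param n string length (>= 1).
#' @param k alphabet size (1..26).
#' @param seed integer seed (mandatory, for reproducibility).
#' @return An `lp_target_system` with the one generated string.
#' @export
random_string <- function(n, k, seed) {
  stopifnot(n >= 1L, k >= 1L, k <= 26L)
  letters_k <- LETTERS[seq_len(k)]
  s <- lp_with_seed(seed, paste(sample(letters_k, n, replace = TRUE),
                                collapse = ""))
  target_system(s)
}

## evaluate `expr` under a local RNG seed, restoring global state after
lp_with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Planted-hierarchy strings with known construction cost
#'
#' Builds a string bottom-up: a random base string over `alphabet`, then
#' `depth` rounds each concatenating `reuse_factor` copies of the previous
#' level.  The planted generation path (base merges, then one
#' `reuse_factor`-ary merge per round, then the take-out) is a valid path,
#' so its length is an upper bound for the exact ladderpath-index of the
#' expanded string.
#'
#' @param depth number of doubling/concatenation rounds (>= 1).
#' @param reuse_factor copies concatenated per round (>= 2).
#' @param alphabet character vector of letters for the base string.
#' @param base_length letters in the level-0 base string.
#' @param seed integer seed.
#' @return A list with `target` (an `lp_target_system`), `planted_cost`
#'   (lifts) and `derivation` (list of ladderon/constituent pairs).
#' @export
planted_hierarchy <- function(depth, reuse_factor = 2L,
                              alphabet = c("A", "B"), base_length = 2L,
                              seed = 1L) {
  stopifnot(depth >= 1L, reuse_factor >= 2L, base_length >= 1L)
  base <- lp_with_seed(seed, paste(sample(alphabet, base_length,
                                          replace = TRUE), collapse = ""))
  derivation <- list(list(ladderon = base,
                          constituents = strsplit(base, "")[[1]]))
  cur <- base
  for (d in seq_len(depth)) {
    nxt <- strrep(cur, reuse_factor)
    derivation[[d + 1L]] <- list(ladderon = nxt,
                                 constituents = rep(cur, reuse_factor))
    cur <- nxt
  }
  planted_cost <- (base_length - 1L) + depth * (reuse_factor - 1L) + 1L
  list(target = target_system(cur), planted_cost = as.integer(planted_cost),
       derivation = derivation)
}
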