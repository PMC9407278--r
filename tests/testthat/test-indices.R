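# Frozen worked values: X = ABCDBCDBCDCDEFEF over A..F, the five-member
# system Q over A..E, and the same X over the extended basic set with BCD.

X <- "ABCDBCDBCDCDEFEF"
bX <- basic_set(LETTERS[1:6])
Q <- target_system(c("ABDEDBED", "ABDED", "ABDABD", "CAB", "ED"),
                   counts = c(2, 1, 1, 2, 3))
bQ <- basic_set(LETTERS[1:5])

test_that("size-index is the minimum basic-token count over all instances", {
  expect_identical(size_index(X, bX), 16L)
  expect_identical(size_index(X, basic_set(c(LETTERS[1:6], "BCD"))), 10L)
  expect_identical(size_index(Q, bQ), 39L)  # 8*2 + 5 + 6 + 3*2 + 2*3
  expect_identical(size_index("A", basic_set(LETTERS)), 1L)
  expect_identical(size_index(target_system("X")[0, ], basic_set("X")), 0L)
})

test_that("the multiset length formula reproduces the worked lengths", {
  jx1 <- parse_pom("{A, B, C, D, E, F // CD, EF // BCD(2)}", bX, X)
  expect_identical(ladderpath_length(jx1), 10L)
  jx2 <- parse_pom("{A, B(2), C(3), D(3), E, F // DBC, EF}", bX, X)
  expect_identical(ladderpath_length(jx2), 13L)
  jx0 <- parse_pom("{A, B(3), C(4), D(4), E(2), F(2)}", bX, X)
  expect_identical(ladderpath_length(jx0), 16L)  # trivial: length = S
  jq <- parse_pom(paste0("{A, B(2), C, D(2), E // AB, ED(4) // CAB, ABD(2)",
                         " // ABDED // ABDEDBED}"), bQ, Q)
  expect_identical(ladderpath_length(jq), 17L)
  expect_identical(order_index(jq), 22L)  # 1 + 1*4 + 2 + 2*2 + 4 + 7
  expect_identical(order_index(jx1), 6L)
  expect_identical(order_index(jx0), 0L)
})

test_that("lambda + omega = S holds identically for arbitrary ladderpaths", {
  for (pom in c("{A, B, C, D, E, F // CD, EF // BCD(2)}",
                "{A, B(2), C(3), D(3), E, F // DBC, EF}",
                "{A, B(3), C(4), D(4), E(2), F(2)}")) {
    lp <- parse_pom(pom, bX, X)
    expect_identical(ladderpath_length(lp) + order_index(lp),
                     size_index(lp$target, lp$basic))
  }
})

test_that("per-letter conservation matches the worked bookkeeping", {
  jx1 <- parse_pom("{A, B, C, D, E, F // CD, EF // BCD(2)}", bX, X)
  cons <- conservation_check(jx1)
  expect_true(all(cons$ok))
  # letter B: once alone, once in each of two BCD uses -> 3 = N_B
  expect_identical(cons$ladderon_count[cons$unit == "B"], 3L)
  expect_identical(cons$target_count[cons$unit == "B"], 3L)
  jq <- parse_pom(paste0("{A, B(2), C, D(2), E // AB, ED(4) // CAB, ABD(2)",
                         " // ABDED // ABDEDBED}"), bQ, Q)
  consq <- conservation_check(jq)
  expect_true(all(consq$ok))
  expect_identical(consq$target_count[consq$unit == "A"], 7L)
  expect_identical(consq$ladderon_count[consq$unit == "A"], 7L)
  # trivial ladderpath: multiplicities are the raw letter counts
  jx0 <- parse_pom("{A, B(3), C(4), D(4), E(2), F(2)}", bX, X)
  expect_true(all(conservation_check(jx0)$ok))
})

test_that("relabeling letters by a bijection leaves all indices unchanged", {
  sigma <- c(A = "Q", B = "R", C = "S", D = "T", E = "U", F = "V")
  relab <- function(s) paste(sigma[strsplit(s, "")[[1]]], collapse = "")
  for (s in c(X, "ABABAB", "AABBAABB")) {
    f1 <- ladderpath(s)
    f2 <- ladderpath(relab(s))
    expect_identical(coef(f1), coef(f2))
  }
})

test_that("degenerate inputs follow the documented conventions", {
  fit1 <- ladderpath("A", basic_set(LETTERS[1:3]))
  expect_identical(coef(fit1), c(S = 1L, lambda = 1L, omega = 0L))
  empty <- target_system("X")[0, ]
  fit0 <- ladderpath(empty, basic_set("X"))
  expect_identical(coef(fit0), c(S = 0L, lambda = 0L, omega = 0L))
})
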