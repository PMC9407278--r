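# The three constructions of X and one of Q, replayed through the multiset
# bookkeeping; lengths and per-operation costs are the worked values.

test_that("replaying the example paths gives the worked lengths and costs", {
  ps <- lp_example_paths()
  s1 <- simulate_path(ps$Ex1)
  expect_identical(s1$length, 10L)
  expect_identical(s1$op_costs, c(1L, 1L, 1L, 6L, 1L))
  s2 <- simulate_path(ps$Ex2)
  expect_identical(s2$length, 13L)
  expect_identical(s2$op_costs, c(2L, 1L, 2L, 1L, 1L, 5L, 1L))
  s3 <- simulate_path(ps$Ex3)
  expect_identical(s3$length, 13L)
  expect_identical(s3$op_costs, c(2L, 1L, 9L, 1L))
  s4 <- simulate_path(ps$Ex4)
  expect_identical(s4$length, 17L)
  expect_identical(s4$op_costs, c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 9L))
})

test_that("paths distill to the expected partially ordered multisets", {
  ps <- lp_example_paths()
  expect_identical(serialize_pom(path_to_ladderpath(ps$Ex1)),
                   "{A, B, C, D, E, F // CD, EF // BCD(2)}")
  # two distinct paths, one ladderpath
  lp2 <- path_to_ladderpath(ps$Ex2)
  lp3 <- path_to_ladderpath(ps$Ex3)
  expect_identical(serialize_pom(lp2),
                   "{A, B(2), C(3), D(3), E, F // DBC, EF}")
  expect_identical(serialize_pom(lp3), serialize_pom(lp2))
  expect_identical(serialize_pom(path_to_ladderpath(ps$Ex4)),
                   paste0("{A, B(2), C, D(2), E // AB, ED(4) // ",
                          "ABD(2), CAB // ABDED // ABDEDBED}"))
})

test_that("path length always equals the distilled ladderpath's length", {
  for (p in lp_example_paths()) {
    expect_identical(simulate_path(p)$length,
                     ladderpath_length(path_to_ladderpath(p)))
  }
})

test_that("illegal operations are rejected with the defining rules", {
  b <- basic_set(c("A", "B"))
  t <- target_system("ABAB")
  # re-generating a block already present in the set
  p1 <- generation_path(list(op_merge(c("A", "B")), op_merge(c("A", "B")),
                             op_takeout("ABAB")), b, t)
  expect_error(simulate_path(p1), "must not be present")
  # taking out a block that was never generated
  p2 <- generation_path(list(op_takeout("ABAB")), b, t)
  expect_error(simulate_path(p2), "never generated")
  # merge output must be the concatenation of its inputs
  expect_error(op_merge(c("A", "B"), "BA"), "concatenation")
  expect_error(op_merge("A"), "at least two")
  # paths must take out every target instance
  p3 <- generation_path(list(op_merge(c("A", "B")),
                             op_merge(c("AB", "AB")),
                             op_takeout("ABAB")),
                        b, target_system("ABAB", counts = 2))
  expect_error(path_to_ladderpath(p3), "exactly 2")
})

test_that("take-outs may pass through negative counts, reflecting reuse", {
  b <- basic_set(c("A", "B"))
  t <- target_system("AB", counts = 3)
  p <- generation_path(list(op_merge(c("A", "B")),
                            op_takeout(c("AB", "AB", "AB"))), b, t)
  sim <- simulate_path(p)
  expect_identical(sim$length, 4L)
  lp <- path_to_ladderpath(p)
  # AB generated once, removed three times: net -2, multiplicity 2
  expect_identical(lp$ladderons$multiplicity[lp$ladderons$block == "AB"], 2L)
  expect_identical(lp$lambda, 4L)
})
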