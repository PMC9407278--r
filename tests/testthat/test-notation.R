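X <- "ABCDBCDBCDCDEFEF"
bX <- basic_set(LETTERS[1:6])

test_that("parsing recovers ladderons, multiplicities and levels", {
  jx1 <- parse_pom("{A, B, C, D, E, F // CD, EF // BCD(2)}", bX, X)
  expect_identical(nrow(jx1$ladderons), 9L)
  expect_identical(jx1$ladderons$level[jx1$ladderons$block == "BCD"], 3L)
  expect_identical(jx1$ladderons$multiplicity[jx1$ladderons$block == "BCD"],
                   2L)
  one <- parse_pom("{A}", basic_set("A"), "A")
  expect_identical(one$ladderons$block, "A")
  expect_identical(one$ladderons$level, 1L)
  Q <- target_system(c("ABDEDBED", "ABDED", "ABDABD", "CAB", "ED"),
                     counts = c(2, 1, 1, 2, 3))
  jq <- parse_pom(paste0("{A,B(2),C,D(2),E // AB,ED(4) // CAB,ABD(2) // ",
                         "ABDED // ABDEDBED}"), basic_set(LETTERS[1:5]), Q)
  expect_identical(nrow(jq$ladderons), 11L)
  expect_identical(max(jq$ladderons$level), 5L)
  expect_identical(jq$ladderons$multiplicity[jq$ladderons$block == "ED"], 4L)
})

test_that("the double-slash glyph is accepted on input", {
  a <- parse_pom("{A,B(2),C(3),D(3),E,F ⫽ DBC,EF}", bX, X)
  b <- parse_pom("{A, B(2), C(3), D(3), E, F // DBC, EF}", bX, X)
  expect_identical(serialize_pom(a), serialize_pom(b))
})

test_that("serialization is canonical: sorted, (1) omitted, ascii levels", {
  jx2 <- parse_pom("{F,E,D(3),C(3),B(2),A // EF,DBC}", bX, X)
  expect_identical(serialize_pom(jx2),
                   "{A, B(2), C(3), D(3), E, F // DBC, EF}")
  jx0 <- parse_pom("{A,B(3),C(4),D(4),E(2),F(2)}", bX, X)
  expect_identical(serialize_pom(jx0), "{A, B(3), C(4), D(4), E(2), F(2)}")
  empty <- parse_pom("{}", bX, target_system(X)[0, ])
  expect_identical(serialize_pom(empty), "{}")
})

test_that("parse and serialize are mutually inverse on canonical forms", {
  poms <- c("{A, B, C, D, E, F // CD, EF // BCD(2)}",
            "{A, B(2), C(3), D(3), E, F // DBC, EF}",
            "{A, B(3), C(4), D(4), E(2), F(2)}")
  for (p in poms)
    expect_identical(serialize_pom(parse_pom(p, bX, X)), p)
})

test_that("malformed notation is rejected with positions", {
  expect_error(parse_pom("A, B // AB", bX, "AB"), "wrapped")
  expect_error(parse_pom("{A, A}", bX, "AA"), "duplicate")
  expect_error(parse_pom("{A(0)}", bX, "A"), "level 1, item 1")
  expect_error(parse_pom("{A // \"B}", bX, "AB"), "unterminated")
})

test_that("blocks with reserved characters survive quoting", {
  b <- basic_set(c("a,b", "(c)"))
  t <- target_system("a,b(c)a,b")
  fit <- ladderpath(t, b, mode = "exact")
  s <- serialize_pom(fit)
  expect_match(s, '"', fixed = TRUE)
  expect_identical(serialize_pom(parse_pom(s, b, t)), s)
})

test_that("laddergraph export follows the drawing conventions", {
  jx1 <- parse_pom("{A, B, C, D, E, F // CD, EF // BCD(2)}", bX, X)
  dot <- export_laddergraph(jx1)
  # transitive reduction: CD reaches the target via BCD only
  expect_false(grepl('"CD" -> "target:ABCDBCDBCDCDEFEF"', dot, fixed = TRUE))
  expect_true(grepl('"CD" -> "BCD"', dot, fixed = TRUE))
  expect_true(grepl('"BCD" -> "target:ABCDBCDBCDCDEFEF"', dot, fixed = TRUE))
  # dimmed basic edges, multiplicity labels, rank groups
  expect_true(grepl('"C" -> "CD" [color=grey70]', dot, fixed = TRUE))
  expect_true(grepl('label="BCD(2)"', dot, fixed = TRUE))
  expect_true(grepl("rank=same", dot, fixed = TRUE))
  # structurally well-formed DOT: balanced braces, digraph header
  expect_identical(lengths(regmatches(dot, gregexpr("{", dot, fixed = TRUE))),
                   lengths(regmatches(dot, gregexpr("}", dot, fixed = TRUE))))
  expect_match(dot, "^digraph")
})

test_that("trivial ladderpaths draw as a dimmed star onto the target", {
  jx0 <- parse_pom("{A, B(3), C(4), D(4), E(2), F(2)}", bX, X)
  g <- ladderpath:::lp_laddergraph(jx0)
  expect_true(all(g$edges$dim))
  expect_true(all(g$edges$to == "target:ABCDBCDBCDCDEFEF"))
})

test_that("system graphs carry multiplicity-prefixed grey target nodes", {
  Q <- target_system(c("ABDEDBED", "ABDED", "ABDABD", "CAB", "ED"),
                     counts = c(2, 1, 1, 2, 3))
  jq <- parse_pom(paste0("{A,B(2),C,D(2),E // AB,ED(4) // CAB,ABD(2) // ",
                         "ABDED // ABDEDBED}"), basic_set(LETTERS[1:5]), Q)
  dot <- export_laddergraph(jq)
  expect_true(grepl("[×2] ABDEDBED", dot, fixed = TRUE))
  expect_true(grepl("(0)", dot, fixed = TRUE))
  g <- ladderpath:::lp_laddergraph(jq)
  expect_identical(sum(!g$nodes$target), 11L)  # one node per block
})
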