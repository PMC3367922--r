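test_that("parsing reads atoms and nesting exactly", {
  f <- parseSExpr("(a (b c))")
  expect_length(f, 1L)
  expect_identical(f[[1]], list("a", list("b", "c")))
  expect_identical(parseSExpr("()")[[1]], list())
  expect_identical(parseSExpr(""), list())
  expect_identical(parseSExpr("x"), list("x"))
  # atom spelling preserved
  expect_identical(parseSExpr("(Rate_1.5e-3 &cat *)")[[1]],
                   list("Rate_1.5e-3", "&cat", "*"))
})

test_that("comments are discarded and multiple top-level forms parse", {
  f <- parseSExpr(c("(a b) ;; trailing comment",
                    ";; whole-line comment",
                    "(c)"))
  expect_length(f, 2L)
  expect_identical(f[[2]], list("c"))
})

test_that("the latent-class chain listing parses as a rate block plus a chain", {
  txt <- "
(rate (s 0.1) (f 2.0) (r_sf 0.01) (r_fs 0.01) (u 1.0))
(chain
 (hidden-class (row CLASS) (label (s f)))
 (terminal RASER))"
  f <- parseSExpr(txt)
  expect_length(f, 2L)
  expect_identical(f[[1]][[1]], "rate")
  expect_identical(f[[2]][[1]], "chain")
})

test_that("malformed input reports a position", {
  expect_error(parseSExpr("(a (b)"), "line 1.*unbalanced|unbalanced")
  expect_error(parseSExpr(c("(a)", " )b")), "line 2")
})

test_that("serialize/parse round trip is structurally identical", {
  set.seed(41)
  randExpr <- function(depth) {
    if (depth == 0 || stats::runif(1) < 0.4)
      return(paste0(sample(c(letters, "_", "*", "0", "9"), 3), collapse = ""))
    lapply(seq_len(sample(0:4, 1)), function(i) randExpr(depth - 1))
  }
  for (rep in 1:25) {
    e <- randExpr(4)
    expect_identical(parseSExpr(writeSExpr(e))[[1]], e)
  }
  # forest writer round trip
  forest <- parseSExpr("(a b) (c (d)) e")
  expect_identical(parseSExpr(writeSExprForest(forest)), forest)
})
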