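dnaEnv <- function(...) macroEnv(tokens = c("a", "c", "g", "t"), ...)

expandText <- function(txt, env = dnaEnv()) {
  expandForest(parseSExpr(txt), env)
}

test_that("string building, conditionals and equality behave as specified", {
  env <- dnaEnv()
  expect_identical(expandMacros(parseSExpr("(&cat r_ 2)")[[1]], env), "r_2")
  expect_identical(expandMacros(parseSExpr("(&if (&eq a a) x y)")[[1]], env),
                   "x")
  expect_identical(expandMacros(parseSExpr("(&if (&eq a b) x y)")[[1]], env),
                   "y")
  # &cat flattens a list argument
  expect_identical(expandMacros(parseSExpr("(&cat (a b c))")[[1]], env),
                   "abc")
  # &neq and numeric comparisons
  expect_identical(expandMacros(parseSExpr("(&if (&neq a b) x y)")[[1]], env),
                   "x")
  expect_identical(expandMacros(parseSExpr("(&if (&gt 3 2) x y)")[[1]], env),
                   "x")
  # &eq compares spellings, the numeric test compares values
  expect_identical(expandMacros(parseSExpr("(&if (&eq 1 1/1) x y)")[[1]],
                                env), "y")
  expect_identical(expandMacros(parseSExpr("(&if (&numeq 1 1/1) x y)")[[1]],
                                env), "x")
})

test_that("arithmetic is exact-rational on integers and supports the inline-division alias", {
  env <- dnaEnv(defines = list(numNonterms = "3"))
  expect_identical(expandMacros(parseSExpr("(&/1 numNonterms)")[[1]], env),
                   "1/3")
  expect_identical(expandMacros(parseSExpr("(&/ 1 3)")[[1]], env), "1/3")
  expect_identical(expandMacros(parseSExpr("(&+ 1/3 1/6)")[[1]], env), "1/2")
  expect_identical(expandMacros(parseSExpr("(&* 2/3 3/4)")[[1]], env), "1/2")
  expect_identical(expandMacros(parseSExpr("(&- numNonterms 1)")[[1]], env),
                   "2")
  expect_equal(atomNumber(expandMacros(parseSExpr("(&* 0.5 3)")[[1]], env)),
               1.5)
  # symbolic division yields the product form (param 1/k)
  expect_identical(expandMacros(parseSExpr("(&/ leaveProb 2)")[[1]], env),
                   list("leaveProb", "1/2"))
  expect_identical(expandMacros(parseSExpr("(&/leaveProb 2)")[[1]], env),
                   list("leaveProb", "1/2"))
  expect_error(expandMacros(parseSExpr("(&/ 1 0)")[[1]], env),
               "division by zero")
})

test_that("the nested token loop of the symmetric DNA chain yields 12 mutate clauses", {
  txt <- "
(&foreach-token tok1
 (&foreach-token tok2
  (&if (&eq tok1 tok2)
   ()
   (mutate (from (tok1)) (to (tok2)) (rate u)))))"
  out <- expandText(txt)
  expect_length(out, 12L)
  expect_true(all(vapply(out, function(e) e[[1]] == "mutate", logical(1))))
  froms <- vapply(out, function(e) e[[2]][[2]][[1]], character(1))
  tos <- vapply(out, function(e) e[[3]][[2]][[1]], character(1))
  expect_false(any(froms == tos))
  expect_identical(sort(unique(froms)), c("a", "c", "g", "t"))
})

test_that("splice-count law: iteration macros splice one copy per element", {
  out <- expandText("(&foreach-token t (x t))")
  expect_length(out, 4L)
  expect_identical(out[[3]], list("x", "g"))
  out <- expandText("(&foreach-integer i (1 7) (r i))")
  expect_length(out, 7L)
  expect_identical(out[[7]], list("r", "7"))
  out <- expandText("(&foreach c (s f) (q c))")
  expect_identical(out, list(list("q", "s"), list("q", "f")))
})

test_that("expansion is a fixed point on macro-free input and deterministic", {
  env <- dnaEnv()
  e <- parseSExpr("(grammar (rate (u 1.0)) (transform (from (a)) (to ())))")[[1]]
  expect_identical(expandMacros(e, env), e)
  txt <- "(&foreach-integer i (1 3) (chain (&cat c_ i) (&/1 i)))"
  a <- expandText(txt)
  b <- expandText(txt)
  expect_identical(a, b)
})

test_that("defines bind values and includes splice other files", {
  out <- expandText("(&define K 4) (&foreach-integer i (1 K) (x i))")
  expect_length(out, 4L)
  inc <- tempfile(fileext = ".eg")
  writeLines("(included a) (&define J 9)", inc)
  out <- expandText(sprintf("(&include %s) (y J)", inc))
  expect_identical(out[[1]], list("included", "a"))
  expect_identical(out[[2]], list("y", "9"))
  expect_error(expandText("(&include /no/such/file.eg)"), "cannot find")
})

test_that("tree iterators require a tree and enumerate labels", {
  expect_error(expandText("(&foreach-node n (x n))"), "no tree")
  tr <- parseNewick("((A:1,B:1)n1:1,C:1)root;")
  env <- dnaEnv(tree = tr)
  nodes <- expandForest(parseSExpr("(&foreach-node n (x n))"), env)
  expect_length(nodes, 5L)
  leaves <- expandForest(parseSExpr("(&foreach-leaf n n)"), env)
  expect_identical(unlist(leaves), c("A", "B", "C"))
  branches <- expandForest(parseSExpr("(&foreach-branch b b)"), env)
  expect_length(branches, 4L)           # every non-root node names a branch
  # list-valued atoms splice in place
  lv <- expandForest(parseSExpr("(x &LEAVES)"), env)
  expect_identical(lv[[1]], list("x", "A", "B", "C"))
})

test_that("unknown macros and missing context are errors, not pass-through", {
  expect_error(expandText("(&bogus x)"), "unknown macro")
  expect_error(expandText("(x &bogus)"), "unknown macro")
  expect_error(expandMacros(parseSExpr("(&foreach-token t t)")[[1]],
                            macroEnv()), "no alphabet")
})

test_that("expanding the rate-multiplier HMM listing gives K nonterminals, chains and rates", {
  for (K in c(1L, 2L, 3L, 5L)) {
    g <- readGrammar(phastconsListing(K))
    expect_length(emittingNonterms(g), K)
    expect_length(grammarChains(g), K)
    rates <- names(grammarParams(g)@rates)
    expect_identical(sort(rates[grepl("^r_", rates)]),
                     sort(paste0("r_", seq_len(K))))
  }
})
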