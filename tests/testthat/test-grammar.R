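test_that("the symmetric DNA grammar validates cleanly", {
  g <- readGrammar(grammarFile("jc69"))
  expect_identical(nrow(validateGrammar(g)), 0L)
  expect_true(isValidGrammar(g))
})

test_that("a non-normalizable probability group yields one diagnostic", {
  g <- readGrammar(grammarFile("phastcons"))
  p <- grammarParams(g)
  p@pgroups$pgroup1 <- c(stayProb = 0.7, leaveProb = 0.1)  # sums to 0.8
  g@params <- p
  d <- validateGrammar(g)
  hits <- grepl("pgroup not normalizable", d$message)
  expect_identical(sum(hits), 1L)
  expect_identical(d$severity[hits], "error")
})

test_that("a simultaneous token-and-class change draws a warning diagnostic", {
  ch <- raserChain()
  ch@mutate <- c(ch@mutate, list(list(from = "a~s", to = "c~f",
                                      expr = "u")))
  rules <- list(
    list(lhs = "start", rhs = "emit", prob = "1"),
    list(lhs = "emit", rhs = c("RASER", "emit*")),
    list(lhs = "emit*", rhs = "emit"),
    list(lhs = "emit", rhs = "emit", prob = "1"),
    list(lhs = "emit", rhs = character(0), prob = "1"))
  g <- makeGrammar("raser+cross", ch@alphabet, list(ch), rules, ch@params)
  d <- validateGrammar(g)
  hits <- grepl("simultaneous token and class change", d$message)
  expect_identical(sum(hits), 1L)
  expect_identical(d$severity[hits], "warning")
})

test_that("undeclared parameters and nonterminals are reported", {
  ch <- jukesCantor()
  rules <- list(
    list(lhs = "start", rhs = "emit", prob = "mystery"),
    list(lhs = "emit", rhs = c("JC", "emit*")),
    list(lhs = "emit*", rhs = "emit"),
    list(lhs = "emit", rhs = character(0), prob = "1"))
  g <- makeGrammar("bad", ch@alphabet, list(ch), rules, ch@params)
  d <- validateGrammar(g)
  expect_true(any(grepl("undeclared parameter: mystery", d$message)))
})

test_that("instantiation follows the printed seed values", {
  # all off-diagonal entries u, diagonal -3u
  rm <- instantiateMatrix(jukesCantor(1))
  off <- rm@Q[row(rm@Q) != col(rm@Q)]
  expect_true(all(abs(off - 1) < 1e-12))
  expect_true(all(abs(diag(rm@Q) + 3) < 1e-12))
  # latent-class chain with printed seeds
  rr <- instantiateMatrix(raserChain())
  expect_equal(rr@Q["a~s", "c~s"], 0.1)
  expect_equal(rr@Q["a~s", "g~s"], 0.1)
  expect_equal(rr@Q["a~s", "a~f"], 0.01)
  expect_equal(rr@Q["g~f", "g~s"], 0.01)
  expect_equal(rr@Q["a~s", "c~f"], 0)
  # all rates zero -> zero generator
  z <- raserChain(0, 0, 0, 0, 0)
  expect_true(all(instantiateMatrix(z)@Q == 0))
})

test_that("generator invariants: row sums, state counts, rate scaling", {
  rr <- instantiateMatrix(raserChain())
  expect_identical(nrow(rr@Q), 8L)
  expect_identical(sum(rr@Q > 0), 32L)   # 24 token changes + 8 class flips
  expect_lt(max(abs(rowSums(rr@Q))), 1e-10)
  ny <- instantiateMatrix(nielsenYang())
  expect_identical(length(ny@Q), 3721L)
  expect_lt(max(abs(rowSums(ny@Q))), 1e-10)
  # scaling every rate parameter by c scales Q by c exactly
  ch <- raserChain()
  p2 <- ch@params
  # u multiplies token changes; class flips are r_sf/r_fs alone: scale all
  p2@rates <- p2@rates * 3
  p2@rates[c("s", "f")] <- ch@params@rates[c("s", "f")]  # s,f multiply u
  Q1 <- instantiateMatrix(ch)@Q
  Q2 <- instantiateMatrix(ch, p2)@Q
  expect_equal(Q2, 3 * Q1, tolerance = 1e-12)
})

test_that("initial distributions default to stationarity (uniform when reducible)", {
  rm <- instantiateMatrix(jukesCantor(0.7))
  expect_equal(rm@pi, rep(0.25, 4))
  # reducible: two disconnected classes -> uniform
  ch <- raserChain(r_sf = 0, r_fs = 0)
  expect_equal(instantiateMatrix(ch)@pi, rep(1 / 8, 8))
  # declared initial entries are normalized and used
  ny <- nielsenYang(pi = NULL)
  expect_equal(sum(instantiateMatrix(ny)@pi), 1, tolerance = 1e-12)
})

test_that("classification separates phylo-HMMs from phylo-SCFGs", {
  expect_identical(classifyGrammar(readGrammar(grammarFile("phastcons"))),
                   "phylo-HMM")
  expect_identical(classifyGrammar(toyPairGrammar()), "phylo-SCFG")
  # adding a bifurcation flips the class
  g <- phastconsHmm(K = 2, rates = c(1, 2))
  g@rules <- c(g@rules, list(list(kind = "bifurcation", lhs = "1",
                                  to = c("1", "2"), prob = "1")))
  expect_identical(classifyGrammar(g), "phylo-SCFG")
})

test_that("the grammar writer is byte-stable and read/write preserves the model", {
  g <- readGrammar(grammarFile("raser"))
  t1 <- writeGrammar(g)
  t2 <- writeGrammar(readGrammar(t1))
  expect_identical(t1, t2)
  g2 <- readGrammar(t1)
  expect_equal(canonicalGrammarSummary(g), canonicalGrammarSummary(g2))
  # hybrid chains survive the round trip too
  gd <- dlessHmm(tree3(), jukesCantor(0.5), slowScale = 0.2)
  gd2 <- readGrammar(writeGrammar(gd))
  expect_equal(canonicalGrammarSummary(gd), canonicalGrammarSummary(gd2))
})
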