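test_that("EM increases the likelihood monotonically on self-simulated data", {
  tr <- tree4()
  g <- readGrammar(grammarFile("jc69"))
  p <- grammarParams(g); p@rates["u"] <- 0.4; grammarParams(g) <- p
  aln <- simulateAlignment(g, tr, length = 300, seed = 21)
  fit <- emTrain(g, aln, tr, maxIter = 8, tol = 1e-8)
  expect_true(all(diff(fit$trace) >= -1e-6 * abs(fit$trace[-1])))
})

test_that("EM recovers a substitution rate from simulated columns", {
  tr <- tree4()
  gTrue <- readGrammar(grammarFile("jc69"))
  p <- grammarParams(gTrue); p@rates["u"] <- 0.3; grammarParams(gTrue) <- p
  aln <- simulateAlignment(gTrue, tr, length = 1500, seed = 22)
  g0 <- gTrue
  p0 <- grammarParams(g0); p0@rates["u"] <- 1; grammarParams(g0) <- p0
  fit <- emTrain(g0, aln, tr, maxIter = 25, tol = 1e-7)
  uHat <- grammarParams(fit$grammar)@rates[["u"]]
  expect_lt(abs(uHat - 0.3) / 0.3, 0.15)
})

test_that("EM renormalizes probability groups from expected usages", {
  tr <- tree4()
  gTrue <- phastconsHmm(K = 2, baseChain = jukesCantor(0.3),
                        rates = c(1 / 3, 3), stayProb = 0.9)
  aln <- simulateAlignment(gTrue, tr, length = 2000, seed = 23)
  g0 <- phastconsHmm(K = 2, baseChain = jukesCantor(0.3),
                     rates = c(1 / 3, 3), stayProb = 0.5)
  fit <- emTrain(g0, aln, tr, maxIter = 20, tol = 1e-7,
                 fix = c("u", "r_1", "r_2"))
  pg <- grammarParams(fit$grammar)@pgroups$trans
  expect_equal(sum(pg), 1, tolerance = 1e-12)
  expect_lt(abs(pg[["stayProb"]] - 0.9), 0.05)
  expect_true(all(diff(fit$trace) >= -1e-6 * abs(fit$trace[-1])))
})

test_that("EM on a phylo-SCFG is monotone and trains the pair rate", {
  g <- toyPairGrammar()
  tr <- tree3()
  aln <- stockholmAlignment(c(A = "acgtacgg", B = "acgaacgg",
                              C = "gcgtatcg"))
  fit <- emTrain(g, aln, tr, maxIter = 4, tol = 1e-8)
  expect_true(all(diff(fit$trace) >= -1e-6 * abs(fit$trace[-1])))
  expect_true(fit$trace[length(fit$trace)] > fit$trace[1])
})

test_that("training requires data and multiple alignments accumulate", {
  g <- readGrammar(grammarFile("jc69"))
  tr <- tree3()
  expect_error(emTrain(g, list(), list()), "no alignments")
  a1 <- simulateAlignment(g, tr, length = 50, seed = 31)
  a2 <- simulateAlignment(g, tr, length = 50, seed = 32)
  fit <- emTrain(g, list(a1, a2), list(tr, tr), maxIter = 3)
  expect_length(fit$trace, fit$iterations + 1L)
})
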