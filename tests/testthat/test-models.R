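test_that("Jukes-Cantor: unit rates, one-substitution calibration, identity limit", {
  rm <- instantiateMatrix(jukesCantor(1))
  expect_true(all(abs(rm@Q[row(rm@Q) != col(rm@Q)] - 1) < 1e-12))
  # u = 1/3 gives one expected substitution per unit time at stationarity
  rm3 <- instantiateMatrix(jukesCantor(1 / 3))
  expect_equal(-sum(rm3@pi * diag(rm3@Q)), 1, tolerance = 1e-12)
  # u -> 0: identity process
  P <- matrixExponential(instantiateMatrix(jukesCantor(1e-12)), 1)
  expect_equal(P, diag(4), tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(jukesCantor(0), "u must be")
})

test_that("latent-class chain: block structure and class lumping", {
  # no class interconversion -> block diagonal across classes
  rm <- instantiateMatrix(raserChain(r_sf = 0, r_fs = 0))
  sIdx <- grep("~s$", rm@states); fIdx <- grep("~f$", rm@states)
  expect_true(all(rm@Q[sIdx, fIdx] == 0))
  expect_true(all(rm@Q[fIdx, sIdx] == 0))
  # s == f: the token-marginal process is Jukes-Cantor scaled by s*u
  ch <- raserChain(s = 0.4, f = 0.4, u = 1.5)
  rm <- instantiateMatrix(ch)
  jc <- instantiateMatrix(jukesCantor(0.4 * 1.5))
  toks <- c("a", "c", "g", "t")
  lump <- matrix(0, 4, 4, dimnames = list(toks, toks))
  for (t1 in toks) for (t2 in toks)
    lump[t1, t2] <- sum(rm@Q[paste0(t1, "~s"), paste0(t2, c("~s", "~f"))])
  diag(lump) <- 0; diag(lump) <- -rowSums(lump)
  expect_equal(lump, jc@Q, tolerance = 1e-12)
})

test_that("discrete-Gamma rates: unit mean, degenerate limits, quadrature oracle", {
  expect_equal(discreteGammaRates(0.5, 1), 1)
  expect_equal(mean(discreteGammaRates(0.3, 7)), 1, tolerance = 1e-8)
  expect_true(all(abs(discreteGammaRates(1e6, 4) - 1) < 1e-2))
  # shape = 1 (exponential), K = 4: numerical integration over quartile bins
  K <- 4
  qs <- stats::qexp(seq(0, 1, length.out = K + 1))
  oracle <- vapply(seq_len(K), function(k) {
    K * stats::integrate(function(x) x * stats::dexp(x), qs[k], qs[k + 1],
                         rel.tol = 1e-10)$value
  }, numeric(1))
  expect_equal(discreteGammaRates(1, 4), oracle, tolerance = 1e-8)
  # rates are increasing across bins
  expect_true(all(diff(discreteGammaRates(0.5, 5)) > 0))
  expect_error(discreteGammaRates(0, 3), "shape")
})

test_that("discrete-Gamma rates agree with the phangorn reference", {
  for (shape in c(0.3, 1, 2.7)) for (K in c(2, 4)) {
    expect_equal(discreteGammaRates(shape, K),
                 as.numeric(phangorn::discrete.gamma(shape, K)),
                 tolerance = 1e-6)
  }
})

test_that("rate-multiplier HMM: transition structure and degenerate K", {
  g <- phastconsHmm(K = 3, rates = c(0.5, 1, 2), stayProb = 0.9)
  hmm <- phygram:::compileHMM(g)
  expect_identical(hmm$states, c("1", "2", "3"))
  expect_equal(unname(diag(hmm$A)), rep(0.9, 3))
  off <- hmm$A[row(hmm$A) != col(hmm$A)]
  expect_equal(unname(off), rep(0.05, 6))     # (1 - 0.9) / 2
  expect_equal(unname(hmm$start), rep(1 / 3, 3))
  expect_equal(unname(hmm$end), rep(1, 3))
  expect_warning(g1 <- phastconsHmm(K = 1, rates = 1, stayProb = 0.8),
                 "forcing stayProb")
  expect_equal(grammarParams(g1)@pgroups$trans[["stayProb"]], 1)
})

test_that("lineage HMM: per-node hybrid chains scale exactly the subtree", {
  tr <- tree4()
  g <- dlessHmm(tr, jukesCantor(1), slowScale = 0.1)
  hybrids <- Filter(function(ch) is(ch, "HybridChain"), grammarChains(g))
  # one hybrid per tree node (4 leaves + 2 internals + root)
  expect_length(hybrids, 7L)
  expect_length(emittingNonterms(g), 8L)      # nodes + background
  # leaf nonterminal: exactly its pendant branch scaled
  hA <- hybrids[["chain_A"]]
  expect_identical(names(hA@components), "A")
  # root nonterminal: every branch scaled (degenerates to a uniformly
  # scaled base chain)
  hRoot <- hybrids[["chain_root"]]
  expect_setequal(names(hRoot@components),
                  setdiff(treeNodeLabels(tr), "root"))
  # internal node: its clade only
  hN1 <- hybrids[["chain_n1"]]
  expect_setequal(names(hN1@components), c("n1", "A", "B"))
})

test_that("codon model: single-nucleotide neighbors only, printed factors", {
  code <- Biostrings::getGeneticCode("1")
  ny <- nielsenYang(code, kappa = 3, omega = 0.4)
  rm <- instantiateMatrix(ny)
  piU <- 1 / 61
  # AAA -> AAG: Lys -> Lys, transition at position 3: kappa * pi
  expect_equal(rm@Q["aaa", "aag"], 3 * piU, tolerance = 1e-12)
  # AAA -> AAC: Lys -> Asn, transversion, nonsynonymous: omega * pi
  expect_equal(rm@Q["aaa", "aac"], 0.4 * piU, tolerance = 1e-12)
  # multi-nucleotide change forbidden
  expect_equal(rm@Q["aaa", "acg"], 0)
  # kappa = omega = 1, uniform pi: all neighbor rates equal
  flat <- instantiateMatrix(nielsenYang(code, kappa = 1, omega = 1))
  nz <- flat@Q[flat@Q > 0 & row(flat@Q) != col(flat@Q)]
  expect_true(all(abs(nz - nz[1]) < 1e-15))
  # each codon has at most 9 single-nucleotide neighbors
  expect_lte(max(rowSums(rm@Q > 0)), 9L)
  expect_lte(sum(rm@Q > 0), 549L)
  # reversibility: pi_i q_ij == pi_j q_ji
  flux <- diag(rm@pi) %*% rm@Q
  expect_lt(max(abs(flux - t(flux))), 1e-14)
  # pair-type classifier
  ty <- codonPairType("aaa", "aag", code)
  expect_identical(ty[c("ndiff", "transition", "synonymous")],
                   list(ndiff = 1L, transition = TRUE, synonymous = TRUE))
  expect_identical(codonPairType("aaa", "acg", code)$ndiff, 2L)
})

test_that("alternate genetic codes change the state space and synonymy", {
  std <- Biostrings::getGeneticCode("1")
  mito <- Biostrings::getGeneticCode("2")   # vertebrate mitochondrial
  expect_identical(length(senseCodons(std)), 61L)
  expect_identical(length(senseCodons(mito)), 60L)
  # AGA codes Arg in the standard code but is a stop in the mitochondrial
  expect_true("aga" %in% senseCodons(std))
  expect_false("aga" %in% senseCodons(mito))
  rmM <- instantiateMatrix(nielsenYang(mito))
  expect_identical(nrow(rmM@Q), 60L)
})

test_that("constructors match macro expansion of the shipped listings", {
  # symmetric DNA chain
  gJC <- readGrammar(grammarFile("jc69"))
  chJC <- grammarChains(gJC)[["JC"]]
  expect_equal(instantiateMatrix(chJC, grammarParams(gJC))@Q,
               instantiateMatrix(jukesCantor(1, terminal = "JC"))@Q)
  # latent-class chain with the printed seeds
  gRA <- readGrammar(grammarFile("raser"))
  chRA <- grammarChains(gRA)[["RASER"]]
  raC <- raserChain()
  expect_equal(instantiateMatrix(chRA, grammarParams(gRA))@Q,
               instantiateMatrix(raC)@Q)
  expect_identical(chRA@classLabels, raC@classLabels)
  expect_identical(chRA@classRow, raC@classRow)
  # rate-multiplier HMM, K = 3, same seeds as the listing
  gM <- readGrammar(grammarFile("phastcons"))
  gC <- phastconsHmm(K = 3, baseChain = namedEntryJC(),
                     rates = rep(0.001, 3), stayProb = 0.9)
  sM <- canonicalGrammarSummary(gM)
  sC <- canonicalGrammarSummary(gC)
  expect_equal(sM$nonterms, sC$nonterms)
  expect_equal(sM$rules, sC$rules)
  expect_equal(sM$params, sC$params)
  for (k in 1:3) {
    key <- paste0("chain_", k)
    expect_equal(sM$chains[[key]]$Q, sC$chains[[key]]$Q)
  }
})
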