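# The single-chain grammar from the shipped listing, with post-emission
# weights stay = 1, end = 1.
singleChainGrammar <- function(u = 1) {
  g <- readGrammar(grammarFile("jc69"))
  p <- grammarParams(g); p@rates["u"] <- u; grammarParams(g) <- p
  g
}

test_that("a single-state grammar's inside total is the product of its parts", {
  g <- singleChainGrammar(0.8)
  tr <- tree3()
  aln <- stockholmAlignment(c(A = "a", B = "c", C = "g"))
  ins <- inside(g, aln, tr)
  jc <- grammarChains(g)[["JC"]]
  colLik <- felsensteinLikelihood(c(A = "a", B = "c", C = "g"), jc, tr,
                                  grammarParams(g))
  # start -> emit (1), emit one column, then stay/end weights 1 each:
  # weight(L=1) = colLik * end
  expect_equal(ins$loglik, log(colLik), tolerance = 1e-12)
  fb <- forwardBackward(g, aln, tr)
  expect_equal(fb$loglik, ins$loglik, tolerance = 1e-12)
  # posteriors are 1 for the only state
  expect_equal(unname(fb$posterior[, 1]), 1)
})

test_that("forward total equals inside total and brute-force path sums", {
  tr <- tree3()
  g <- phastconsHmm(K = 2, baseChain = jukesCantor(0.5), rates = c(0.3, 3),
                    stayProb = 0.85)
  aln <- stockholmAlignment(c(A = "aacgt", B = "acccn", C = "g-cgt"))
  fb <- forwardBackward(g, aln, tr)
  ins <- inside(g, aln, tr)
  expect_equal(fb$loglik, ins$loglik, tolerance = 1e-9)
  # enumeration over the 2^5 hidden-state paths
  hmm <- phygram:::compileHMM(g)
  rows <- phygram:::asRowMatrix(aln)
  emis <- matrix(0, 2, 5)
  for (k in 1:2) for (i in 1:5) {
    col <- setNames(rows[, i], rownames(rows))
    emis[k, i] <- felsensteinLikelihood(
      col, grammarChains(g)[[hmm$chainKey[k]]], tr, grammarParams(g))
  }
  oracle <- enumerateHmmPaths(hmm$states, hmm$start, hmm$A, hmm$end, emis, 5)
  expect_equal(fb$loglik, log(oracle), tolerance = 1e-9)
  # per-column posteriors sum to one
  expect_lt(max(abs(rowSums(fb$posterior) - 1)), 1e-9)
  # an inactive band reproduces the unbanded likelihood
  expect_equal(inside(g, aln, tr, band = 5)$loglik, ins$loglik,
               tolerance = 1e-12)
})

test_that("degenerate HMMs have trivial posteriors", {
  tr <- tree3()
  aln <- stockholmAlignment(c(A = "acgt", B = "aggt", C = "acct"))
  suppressWarnings(g1 <- phastconsHmm(K = 1, rates = 1, stayProb = 1))
  fb1 <- forwardBackward(g1, aln, tr)
  expect_equal(unname(fb1$posterior[, 1]), rep(1, 4))
  # two states with identical chains: posteriors 0.5 by symmetry
  g2 <- phastconsHmm(K = 2, rates = c(1, 1), stayProb = 0.7)
  fb2 <- forwardBackward(g2, aln, tr)
  expect_equal(unname(fb2$posterior), matrix(0.5, 4, 2), tolerance = 1e-9)
  # forward-backward refuses a phylo-SCFG
  expect_error(forwardBackward(toyPairGrammar(), aln, tr), "phylo-SCFG")
})

test_that("inside matches exhaustive parse enumeration on a pair grammar", {
  g <- toyPairGrammar()
  tr <- tree3()
  rows <- phygram:::asRowMatrix(
    stockholmAlignment(c(A = "acgtac", B = "acgaac", C = "gcgtat")))
  ins <- inside(g, rows, tr)
  oracle <- enumerateScfg(g, rows, tr, what = "sum")
  expect_equal(ins$loglik, log(oracle), tolerance = 1e-9)
  # shorter alignments, odd and even
  for (L in 2:4) {
    sub <- rows[, seq_len(L), drop = FALSE]
    expect_equal(inside(g, sub, tr)$loglik,
                 log(enumerateScfg(g, sub, tr, what = "sum")),
                 tolerance = 1e-9)
  }
})

test_that("CYK finds the exhaustive best parse and never exceeds inside", {
  g <- toyPairGrammar()
  tr <- tree3()
  rows <- phygram:::asRowMatrix(
    stockholmAlignment(c(A = "acgtac", B = "acgaac", C = "gcgtat")))
  ck <- cyk(g, rows, tr)
  ins <- inside(g, rows, tr)
  expect_lte(ck$logscore, ins$loglik)
  oracle <- enumerateScfg(g, rows, tr, what = "max")
  expect_equal(ck$logscore, log(oracle), tolerance = 1e-9)
  # deterministic repetition
  ck2 <- cyk(g, rows, tr)
  expect_identical(ck$labels, ck2$labels)
  expect_equal(ck$logscore, ck2$logscore)
  # single-parse grammar: CYK equals inside exactly
  g1 <- singleChainGrammar(1)
  g1@rules <- Filter(function(r)
    !(r$kind %in% c("transition", "return") && r$lhs == "emit"), g1@rules)
  a1 <- stockholmAlignment(c(A = "a", B = "c", C = "g"))
  expect_equal(cyk(g1, a1, tr)$logscore, inside(g1, a1, tr)$loglik,
               tolerance = 1e-12)
})

test_that("banding excludes distant pairs monotonically", {
  g <- toyPairGrammar()
  tr <- tree3()
  rows <- phygram:::asRowMatrix(
    stockholmAlignment(c(A = "acgtac", B = "acgaac", C = "gcgtat")))
  lls <- vapply(1:6, function(N) inside(g, rows, tr, band = N)$loglik,
                numeric(1))
  expect_true(all(diff(lls) >= -1e-12))
  expect_equal(lls[6], inside(g, rows, tr)$loglik, tolerance = 1e-12)
  expect_lt(lls[1], lls[6])    # the tight band really removes pairings
})

test_that("inside-outside posteriors are normalized and localize structure", {
  g <- toyPairGrammar()
  tr <- tree3()
  rows <- phygram:::asRowMatrix(
    stockholmAlignment(c(A = "acgtac", B = "acgaac", C = "gcgtat")))
  io <- insideOutside(g, rows, tr)
  expect_lt(max(abs(rowSums(io$posterior) - 1)), 1e-9)
  expect_equal(io$loglik, inside(g, rows, tr)$loglik, tolerance = 1e-12)
})

test_that("annotation produces consistent labels, GFF runs and class rows", {
  tr <- tree4()
  g <- phastconsHmm(K = 2, baseChain = jukesCantor(0.4), rates = c(0.2, 3),
                    stayProb = 0.9)
  aln <- simulateAlignment(g, tr, length = 40, seed = 5)
  pa <- annotateAlignment(g, aln, tr, ancestral = TRUE)
  expect_length(pa@labels, 40L)
  expect_true(all(pa@labels %in% emittingNonterms(g)))
  # GFF runs tile the alignment and agree with the #=GC string
  expect_equal(sum(pa@gff$end - pa@gff$start + 1), 40)
  gcChars <- strsplit(pa@gc[["RATE"]], "")[[1]]
  for (q in seq_len(nrow(pa@gff)))
    expect_true(all(gcChars[pa@gff$start[q]:pa@gff$end[q]] ==
                    pa@gff$type[q]))
  # ancestral rows cover all internal nodes, over alphabet tokens
  expect_setequal(names(pa@ancestral), c("root", "n1", "n2"))
  expect_true(all(strsplit(pa@ancestral[["root"]], "")[[1]] %in%
                  c("a", "c", "g", "t")))
  # one-state grammar: a single feature spanning the whole alignment
  suppressWarnings(g1 <- phastconsHmm(K = 1, rates = 1))
  pa1 <- annotateAlignment(g1, aln, tr)
  expect_identical(nrow(pa1@gff), 1L)
  expect_identical(c(pa1@gff$start, pa1@gff$end), c(1L, 40L))
})

test_that("latent-class grammars annotate #=GR class rows", {
  tr <- tree3()
  g <- readGrammar(grammarFile("raser"))
  aln <- simulateAlignment(g, tr, length = 30, seed = 9)
  pa <- annotateAlignment(g, aln, tr)
  expect_setequal(names(pa@gr), c("A", "B", "C"))
  chars <- strsplit(pa@gr[["A"]][["CLASS"]], "")[[1]]
  expect_length(chars, 30L)
  expect_true(all(chars %in% c("s", "f")))
})
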