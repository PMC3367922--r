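test_that("sampling is reproducible under a fixed seed", {
  tr <- tree4()
  g <- phastconsHmm(K = 2, rates = c(0.5, 2), stayProb = 0.8)
  a1 <- simulateAlignment(g, tr, length = 30, seed = 101)
  a2 <- simulateAlignment(g, tr, length = 30, seed = 101)
  expect_identical(alignmentRows(a1), alignmentRows(a2))
  expect_identical(a1@gc, a2@gc)
  a3 <- simulateAlignment(g, tr, length = 30, seed = 102)
  expect_false(identical(alignmentRows(a1), alignmentRows(a3)))
})

test_that("sampled state paths follow the transition probabilities", {
  g <- phastconsHmm(K = 2, rates = c(0.5, 2), stayProb = 0.9)
  parse <- sampleParse(g, length = 10000, seed = 103)
  st <- parse$states
  selfFreq <- mean(st[-1] == st[-length(st)])
  # binomial sampling error over ~10,000 steps is well under 0.01
  expect_lt(abs(selfFreq - 0.9), 0.01)
})

test_that("a single-parse grammar always yields its one parse", {
  g <- readGrammar(grammarFile("jc69"))
  g@rules <- Filter(function(r)
    !(r$kind %in% c("transition", "return") && r$lhs == "emit"), g@rules)
  parse <- sampleParse(g, seed = 104)
  expect_identical(parse$length, 1L)
  expect_identical(parse$states, "emit")
})

test_that("zero-length branches copy the root tuple to every leaf", {
  tr <- parseNewick("(A:0,B:0,C:0)root;")
  g <- readGrammar(grammarFile("jc69"))
  aln <- simulateAlignment(g, tr, length = 25, seed = 105)
  rows <- alignmentRows(aln)
  expect_identical(rows[["A"]], rows[["B"]])
  expect_identical(rows[["A"]], rows[["C"]])
})

test_that("a long branch randomizes leaf tokens to the stationary uniform", {
  tr <- parseNewick("(A:0.0001,B:100);")
  g <- readGrammar(grammarFile("jc69"))
  aln <- simulateAlignment(g, tr, length = 10000, seed = 106)
  freqs <- table(strsplit(alignmentRows(aln)[["B"]], "")[[1]]) / 10000
  se3 <- 3 * sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(freqs - 0.25) < se3))
})

test_that("event-path sampling matches the generator's substitution rate", {
  # u = 1/3: one expected substitution per site per unit time
  counts <- samplePathCounts(jukesCantor(1 / 3), t = 2, n = 4000,
                             seed = 107)
  rate <- mean(counts) / 2
  se3 <- 3 * sqrt(stats::var(counts) / 4000) / 2
  expect_lt(abs(rate - 1), se3 + 0.02)
})

test_that("hidden-class truth is written to #=GR and parse truth to #=GC", {
  tr <- tree3()
  g <- readGrammar(grammarFile("raser"))
  aln <- simulateAlignment(g, tr, length = 20, seed = 108)
  expect_setequal(names(aln@gr), c("A", "B", "C"))
  expect_true(all(strsplit(aln@gr[["A"]][["CLASS"]], "")[[1]] %in%
                  c("s", "f")))
  expect_identical(nchar(aln@gc[["STATE"]]), 20L)
})

test_that("data simulated under a model scores higher under it than a mismatch", {
  tr <- tree4()
  fast <- readGrammar(grammarFile("jc69"))
  pF <- grammarParams(fast); pF@rates["u"] <- 1; grammarParams(fast) <- pF
  slow <- fast
  pS <- grammarParams(slow); pS@rates["u"] <- 0.05; grammarParams(slow) <- pS
  wins <- 0L
  nrep <- 12L
  for (r in seq_len(nrep)) {
    aln <- simulateAlignment(fast, tr, length = 400, seed = 200 + r)
    la <- forwardBackward(fast, aln, tr)$loglik
    lb <- forwardBackward(slow, aln, tr)$loglik
    if (la > lb) wins <- wins + 1L
  }
  expect_gte(wins / nrep, 0.95)
})
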