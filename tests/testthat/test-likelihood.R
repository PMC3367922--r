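test_that("matrix exponential: identity at t=0, closed form, stationarity limit", {
  rm <- instantiateMatrix(jukesCantor(1 / 3))
  expect_equal(matrixExponential(rm, 0), diag(4), ignore_attr = TRUE)
  # stay-probability 1/4 + (3/4) exp(-4ut) at u = 1/3, t = 1
  P <- matrixExponential(rm, 1)
  expect_equal(P[1, 1], 0.25 + 0.75 * exp(-4 / 3), tolerance = 1e-12)
  expect_equal(P[1, 2], 0.25 - 0.25 * exp(-4 / 3), tolerance = 1e-12)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  # long branch: every row approaches the stationary distribution (from
  # the null space of t(Q))
  rr <- instantiateMatrix(raserChain(r_sf = 0.5, r_fs = 0.25))
  ns <- svd(t(rr@Q))
  statio <- abs(ns$v[, ncol(ns$v)]); statio <- statio / sum(statio)
  Pinf <- matrixExponential(rr, 60)
  for (i in seq_len(nrow(Pinf)))
    expect_equal(unname(Pinf[i, ]), unname(statio), tolerance = 1e-8)
  expect_error(matrixExponential(rm, -1), ">= 0")
})

test_that("eigendecomposition and scaling-and-squaring exponentials agree", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    Q <- matrix(stats::rexp(n * n), n, n)
    diag(Q) <- 0; diag(Q) <- -rowSums(Q)
    t <- stats::runif(1, 0.01, 2)
    P1 <- matrixExponential(Q, t)
    P2 <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
    expect_equal(P1, P2, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("pruning equals brute-force enumeration on small trees and chains", {
  set.seed(23)
  chains <- list(jukesCantor(0.7), raserChain())
  for (ch in chains) {
    toks <- alphabetTokens(ch@alphabet)
    for (n in 2:4) {
      tr <- randomTree(n)
      col <- setNames(sample(c(toks, "n"), n, replace = TRUE),
                      treeLeafLabels(tr))
      lik <- felsensteinLikelihood(col, ch, tr)
      oracle <- bruteForceColumnLik(ch, tr, col = col)
      expect_equal(lik, oracle, tolerance = 1e-9)
    }
  }
})

test_that("degenerate columns have closed-form likelihoods", {
  jc <- jukesCantor(1)
  # zero branch lengths: stationary probability of the shared token
  expect_equal(felsensteinLikelihood(c(A = "a", B = "a"),
                                     jc, parseNewick("(A:0,B:0);")), 0.25)
  # infinite branches: independent stationary draws
  expect_equal(felsensteinLikelihood(c(A = "a", B = "c"), jc,
                                     parseNewick("(A:100,B:100);")),
               1 / 16, tolerance = 1e-9)
  # all-wildcard column: likelihood exactly 1
  expect_equal(felsensteinLikelihood(c(A = "*", B = "n", C = "-"), jc,
                                     tree3()), 1)
  # a missing leaf is an error naming it
  expect_error(felsensteinLikelihood(c(A = "a", B = "c"), jc, tree3()),
               "C")
})

test_that("root placement is irrelevant for reversible chains", {
  set.seed(31)
  tr <- tree4()
  jc <- jukesCantor(0.4)
  for (rep in 1:5) {
    col <- setNames(sample(c("a", "c", "g", "t"), 4, replace = TRUE),
                    treeLeafLabels(tr))
    base <- felsensteinLikelihood(col, jc, tr)
    for (node in c("n1", "n2", "A", "D")) {
      re <- rerootTree(tr, node)
      expect_equal(felsensteinLikelihood(col, jc, re), base,
                   tolerance = 1e-9)
    }
  }
})

test_that("hybrid chains resolve per branch and collapse when uniform", {
  tr <- tree3()
  base <- jukesCantor(0.5)
  slow <- scaleChain(base, "0.1")
  # identical components: indistinguishable from the plain chain
  hSame <- hybridChain("H", list(A = base, B = base), base)
  col <- c(A = "a", B = "c", C = "g")
  expect_lt(abs(felsensteinLikelihood(col, hSame, tr, base@params) -
                felsensteinLikelihood(col, base, tr)), 1e-12)
  # scaled components change the likelihood and match brute force
  hMix <- hybridChain("H", list(A = slow, n1 = slow), base)
  lik <- felsensteinLikelihood(col, hMix, tr, base@params)
  expect_false(abs(lik - felsensteinLikelihood(col, base, tr)) < 1e-12)
  expect_equal(lik, bruteForceColumnLik(hMix, tr, base@params, col),
               tolerance = 1e-9)
})

test_that("ancestral posteriors follow Bayes rule and point masses at leaves", {
  jc <- jukesCantor(0.6)
  tr <- tree3()
  # observed leaf: point mass
  post <- ancestralMarginal(c(A = "g", B = "a", C = "t"), jc, tr,
                            node = "A")
  expect_equal(unname(post["g"]), 1)
  # star tree with zero lengths: root must carry the shared token
  star <- parseNewick("(A:0,B:0,C:0)root;")
  post <- ancestralMarginal(c(A = "g", B = "g", C = "g"), jc, star,
                            node = "root")
  expect_equal(unname(post["g"]), 1)
  # general case: enumeration oracle
  set.seed(47)
  for (rep in 1:5) {
    col <- setNames(sample(c("a", "c", "g", "t", "*"), 3, replace = TRUE),
                    c("A", "B", "C"))
    for (node in c("root", "n1")) {
      post <- ancestralMarginal(col, jc, tr, node = node)
      oracle <- bruteForceAncestral(jc, tr, col = col, node = node)
      expect_equal(unname(post), oracle, tolerance = 1e-9)
      expect_equal(sum(post), 1, tolerance = 1e-9)
    }
  }
  expect_error(ancestralMarginal(c(A = "a", B = "c", C = "g"), jc, tr,
                                 node = "nope"), "not in tree")
})

test_that("the most probable ancestral state is the posterior argmax", {
  set.seed(53)
  ra <- raserChain()
  for (rep in 1:20) {
    n <- sample(2:4, 1)
    tr <- randomTree(n)
    col <- setNames(sample(c("a", "c", "g", "t"), n, replace = TRUE),
                    treeLeafLabels(tr))
    node <- sample(treeNodeLabels(tr), 1)
    post <- ancestralMarginal(col, ra, tr, node = node)
    expect_identical(ancestralArgmax(col, ra, tr, node = node),
                     names(post)[which.max(post)])
  }
})

test_that("branch count integrals: eigen route matches quadrature", {
  set.seed(61)
  for (ch in list(jukesCantor(0.8), raserChain())) {
    rm <- instantiateMatrix(ch)
    S <- nrow(rm@Q)
    C <- matrix(stats::runif(S * S), S, S)
    C <- C * matrixExponential(rm, 0.7)    # plausible endpoint posterior
    a <- branchExpectedCounts(rm, 0.7, C, method = "eigen")
    b <- branchExpectedCounts(rm, 0.7, C, method = "quadrature")
    expect_equal(a$subs, b$subs, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(a$wait, b$wait, tolerance = 1e-6)
    # total wait time equals branch length times total endpoint weight
    expect_equal(sum(a$wait), 0.7 * sum(C), tolerance = 1e-8)
    expect_true(all(a$subs >= 0) && all(a$wait >= 0))
  }
})
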