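## Expected substitution counts and state wait times along branches,
## conditioned on endpoint-pair posteriors: the chain part of the EM
## E-step.  The closed form uses the generator's eigendecomposition; a
## numerical quadrature of the interval integral is the fallback for
## non-diagonalizable generators (and the cross-check in tests).

## J integral: J[a,b] = int_0^t exp(la*s + lb*(t-s)) ds.
eigenJ <- function(values, t) {
  n <- length(values)
  la <- matrix(values, n, n)
  lb <- t(la)
  dd <- la - lb
  J <- matrix(0, n, n)
  small <- abs(dd) < 1e-9
  J[!small] <- (exp(la[!small] * t) - exp(lb[!small] * t)) / dd[!small]
  J[small] <- t * exp(la[small] * t)
  J
}

#' Expected substitution counts on one branch
#'
#' Given a generator Q, a branch length t, and a matrix \code{C} of expected
#' endpoint-pair counts (\code{C[k, l]} = expected number of times the
#' branch starts in state k and ends in state l, from the tree-level
#' posterior), returns the expected number of i->j substitution events and
#' the expected time spent in each state, integrated along the branch.
#'
#' @param rm a \code{\link{RateMatrix}} (or plain generator matrix).
#' @param t branch length.
#' @param C endpoint-pair count matrix (states x states).
#' @param method \code{"eigen"} (default, with automatic fallback) or
#'   \code{"quadrature"}.
#' @return list with \code{subs} (matrix of expected i->j event counts,
#'   zero diagonal) and \code{wait} (expected occupancy times).
#' @export
branchExpectedCounts <- function(rm, t, C, method = c("eigen", "quadrature")) {
  method <- match.arg(method)
  Q <- if (is(rm, "RateMatrix")) rm@Q else rm
  n <- nrow(Q)
  if (t == 0 || sum(C) == 0) {
    return(list(subs = matrix(0, n, n, dimnames = dimnames(Q)),
                wait = setNames(rep(0, n), rownames(Q))))
  }
  P <- matrixExponential(Q, t)
  Cp <- C
  pos <- C > 0
  Cp[pos] <- C[pos] / pmax(P[pos], 1e-300)
  Cp[!pos] <- 0
  M <- NULL
  if (method == "eigen") {
    ed <- chainEigen(Q)
    if (!is.null(ed)) {
      W <- t(ed$V) %*% Cp %*% t(ed$Vi)
      J <- eigenJ(ed$values, t)
      M <- Re(t(ed$Vi) %*% (J * W) %*% t(ed$V))
    }
  }
  if (is.null(M)) {
    ## Simpson quadrature of int_0^t P(s)^T C' P(t-s)^T ds
    K <- 40L
    ss <- seq(0, t, length.out = K + 1L)
    h <- t / K
    wts <- c(1, rep(c(4, 2), length.out = K - 1L), 1) * h / 3
    Ps <- lapply(ss, function(s) matrixExponential(Q, s))
    M <- matrix(0, n, n)
    for (k in seq_along(ss))
      M <- M + wts[k] * (t(Ps[[k]]) %*% Cp %*% t(Ps[[K + 2L - k]]))
  }
  M[M < 0] <- 0
  subs <- Q * M
  diag(subs) <- 0
  subs[subs < 0] <- 0
  list(subs = subs, wait = setNames(pmax(diag(M), 0), rownames(Q)))
}

## Expected endpoint-pair counts per edge for one chain, given the pruning
## structures and per-column emission weights w (expected number of times
## the chain emits each observation column).  Returns per-component summed
## substitution counts and wait times.
chainSubstitutionCounts <- function(engine, pr, out, w) {
  edges <- engine$edges
  comps <- unique(engine$compKey)
  subs <- lapply(comps, function(k) {
    S <- pr$S
    matrix(0, S, S)
  })
  names(subs) <- comps
  wait <- lapply(comps, function(k) rep(0, pr$S))
  names(wait) <- comps
  for (i in seq_len(nrow(edges))) {
    A <- out$excl[[i]]
    B <- pr$F[[edges$child[i]]]
    P <- engine$P[[i]]
    Z <- colSums(A * (P %*% B))
    use <- which(w > 0 & Z > 0)
    if (!length(use)) next
    Aw <- A[, use, drop = FALSE] *
      rep(w[use] / Z[use], each = nrow(A))
    C <- P * (Aw %*% t(B[, use, drop = FALSE]))
    k <- engine$compKey[i]
    bc <- branchExpectedCounts(engine$inst$mats[[k]], edges$length[i], C)
    subs[[k]] <- subs[[k]] + bc$subs
    wait[[k]] <- wait[[k]] + bc$wait
  }
  list(subs = subs, wait = wait)
}

## Outside pass variant that also keeps, for every edge, the "exclusion"
## outside vector at the parent (everything except the edge's own subtree).
outsideColumnsFull <- function(engine, pr) {
  nn <- length(pr$F)
  D <- vector("list", nn)
  excl <- vector("list", nrow(engine$edges))
  D[[engine$root]] <- matrix(engine$rootPi, pr$S, pr$U)
  edges <- engine$edges
  for (i in rev(seq_len(nrow(edges)))) {
    p <- edges$parent[i]; c <- edges$child[i]
    sibs <- which(edges$parent == p)
    ex <- D[[p]]
    for (j in sibs) {
      if (j == i) next
      ex <- ex * (engine$P[[j]] %*% pr$F[[edges$child[j]]])
    }
    excl[[i]] <- ex
    Dc <- crossprod(engine$P[[i]], ex)
    mx <- apply(Dc, 2L, max)
    mx[mx <= 0] <- 1
    D[[c]] <- sweep(Dc, 2L, mx, "/")
  }
  list(D = D, excl = excl)
}

## Tie substitution counts to the chain's parametric structure: for each
## rate parameter, accumulate the expected event count over all mutate
## entries whose expression contains it, and the correspondingly weighted
## wait time (product of the entry's other factors).
accumulateRateStats <- function(chain, params, subs, wait, acc) {
  for (m in chain@mutate) {
    fi <- match(m$from, chain@stateNames)
    ti <- match(m$to, chain@stateNames)
    pnames <- m$expr[is.na(vapply(m$expr, atomNumber, numeric(1)))]
    for (pn in unique(pnames)) {
      if (!(pn %in% names(params@rates))) next   # consts are not trained
      others <- m$expr[-match(pn, m$expr)]       # drop one occurrence
      aij <- evalExpr(others, params)
      if (is.null(acc[[pn]])) acc[[pn]] <- c(num = 0, den = 0)
      acc[[pn]]["num"] <- acc[[pn]]["num"] + subs[fi, ti]
      acc[[pn]]["den"] <- acc[[pn]]["den"] + wait[fi] * aij
    }
  }
  acc
}
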