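## Per-column phylogenetic likelihood: matrix exponentials, Felsenstein
## pruning (vectorized over columns, with per-node scaling), the outside
## pass on the tree, and marginal ancestral reconstruction.

#' Matrix exponential of a rate generator
#'
#' Computes exp(Qt) by eigendecomposition when the generator is
#' diagonalizable to machine tolerance, falling back to scaling-and-squaring
#' (\code{Matrix::expm}) otherwise.  Entries below zero by rounding are
#' clamped to 0; rows sum to 1 within 1e-10.
#'
#' @param Q a generator matrix or \code{\link{RateMatrix}}.
#' @param t branch length (>= 0).
#' @return a row-stochastic matrix.
#' @export
matrixExponential <- function(Q, t) {
  if (is(Q, "RateMatrix")) Q <- Q@Q
  if (t < 0) stop("branch length must be >= 0", call. = FALSE)
  n <- nrow(Q)
  if (t == 0 || all(Q == 0)) return(diag(n))
  P <- NULL
  ed <- chainEigen(Q)
  if (!is.null(ed)) {
    P <- Re(ed$V %*% (exp(ed$values * t) * ed$Vi))
  }
  if (is.null(P) || any(P < -1e-9) || any(abs(rowSums(P) - 1) > 1e-9)) {
    P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
  }
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

## Eigendecomposition with inverse, or NULL if numerically unreliable.
chainEigen <- function(Q) {
  ed <- tryCatch(eigen(Q), error = function(e) NULL)
  if (is.null(ed)) return(NULL)
  Vi <- tryCatch(solve(ed$vectors), error = function(e) NULL)
  if (is.null(Vi)) return(NULL)
  ## reconstruction check: Q == V diag(values) Vi
  rec <- Re(ed$vectors %*% (ed$values * Vi))
  if (max(abs(rec - Q)) > 1e-8 * max(1, max(abs(Q)))) return(NULL)
  list(values = ed$values, V = ed$vectors, Vi = Vi)
}

## ---- engine: per-(chain, tree, params) precomputation ----------------------

## Instantiate every distinct component of a (possibly hybrid) chain.
## Returns list(byLabel = label -> component key, mats = key -> RateMatrix,
##              chains = key -> Chain).
chainInstances <- function(chain, params) {
  if (is(chain, "HybridChain")) {
    mats <- list(default = instantiateMatrix(chain@default, params))
    chs <- list(default = chain@default)
    byLabel <- character(0)
    for (nm in names(chain@components)) {
      key <- paste0("component:", nm)
      mats[[key]] <- instantiateMatrix(chain@components[[nm]], params)
      chs[[key]] <- chain@components[[nm]]
      byLabel[nm] <- key
    }
    list(byLabel = byLabel, mats = mats, chains = chs,
         template = chain@default)
  } else {
    list(byLabel = character(0),
         mats = list(default = instantiateMatrix(chain, params)),
         chains = list(default = chain), template = chain)
  }
}

## Build the per-branch engine: edges in postorder with resolved component
## keys and cached transition matrices (the BranchMatrixCache).
chainEngine <- function(chain, tree, params) {
  inst <- chainInstances(chain, params)
  edges <- treeEdgeTable(tree)
  compKey <- vapply(edges$childLabel, function(lab) {
    k <- inst$byLabel[lab]
    if (is.na(k)) "default" else unname(k)
  }, character(1))
  cache <- new.env(parent = emptyenv())
  P <- vector("list", nrow(edges))
  for (i in seq_len(nrow(edges))) {
    key <- paste0(compKey[i], "@", formatNum(edges$length[i]))
    if (is.null(cache[[key]]))
      cache[[key]] <- matrixExponential(inst$mats[[compKey[i]]],
                                        edges$length[i])
    P[[i]] <- cache[[key]]
  }
  phy <- tree@phylo
  list(inst = inst, edges = edges, compKey = compKey, P = P,
       tree = tree, ntip = length(phy$tip.label),
       root = length(phy$tip.label) + 1L,
       labels = c(phy$tip.label, phy$node.label),
       template = inst$template,
       rootPi = inst$mats[["default"]]@pi,
       states = inst$mats[["default"]]@states)
}

## Leaf indicator vectors over chain states for one observed tuple string.
tupleIndicator <- function(chain, tupleChars) {
  S <- nStates(chain)
  v <- rep(1, S)
  arity <- length(chain@terminals)
  if (length(tupleChars) != arity)
    stop("tuple arity mismatch: expected ", arity, " characters",
         call. = FALSE)
  for (p in seq_len(arity)) {
    ch <- tupleChars[p]
    if (ch %in% chain@alphabet@tokens)
      v <- v * as.numeric(chain@stateTokens[, p] == ch)
    ## wildcard / gap / unknown: all states possible at this position
  }
  v
}

## Pruning up-pass, vectorized over U observation columns.
## tuples: character matrix (leaves x U) of concatenated tuple characters,
## rownames = leaf labels.  Returns per-node S x U partial likelihoods with
## per-column log scale factors, plus total log-likelihood per column.
pruneColumns <- function(engine, tuples) {
  chainT <- engine$template
  S <- nStates(chainT)
  U <- ncol(tuples)
  arity <- length(chainT@terminals)
  nn <- engine$ntip + engine$tree@phylo$Nnode
  F <- vector("list", nn)
  logScale <- matrix(0, nn, U)
  leafIdx <- match(rownames(tuples), engine$labels)
  if (any(is.na(leafIdx)))
    stop("alignment row with no tree leaf: ",
         paste(rownames(tuples)[is.na(leafIdx)], collapse = ", "),
         call. = FALSE)
  if (!all(seq_len(engine$ntip) %in% leafIdx))
    stop("tree leaf missing from the observations: ",
         paste(engine$labels[setdiff(seq_len(engine$ntip), leafIdx)],
               collapse = ", "), call. = FALSE)
  for (r in seq_len(nrow(tuples))) {
    obs <- tuples[r, ]
    uniq <- unique(obs)
    M <- matrix(0, S, U)
    for (u in uniq) {
      ind <- tupleIndicator(chainT, strsplit(u, "")[[1L]])
      M[, obs == u] <- ind
    }
    F[[leafIdx[r]]] <- M
  }
  edges <- engine$edges
  for (i in seq_len(nrow(edges))) {
    p <- edges$parent[i]; c <- edges$child[i]
    contrib <- engine$P[[i]] %*% F[[c]]
    if (is.null(F[[p]])) {
      F[[p]] <- contrib
      logScale[p, ] <- logScale[c, ]
    } else {
      F[[p]] <- F[[p]] * contrib
      logScale[p, ] <- logScale[p, ] + logScale[c, ]
    }
    if (i == nrow(edges) || edges$parent[i + 1L] != p) {
      mx <- apply(F[[p]], 2L, max)
      mx[mx <= 0] <- 1
      F[[p]] <- sweep(F[[p]], 2L, mx, "/")
      logScale[p, ] <- logScale[p, ] + log(mx)
    }
  }
  rootLik <- as.numeric(engine$rootPi %*% F[[engine$root]])
  list(F = F, logScale = logScale,
       loglik = log(rootLik) + logScale[engine$root, ],
       U = U, S = S)
}

## Outside (down) pass: per-node S x U vectors D such that the posterior of
## the state at node n is proportional to D[[n]] * F[[n]] columnwise.
outsideColumns <- function(engine, pr) {
  nn <- length(pr$F)
  D <- vector("list", nn)
  D[[engine$root]] <- matrix(engine$rootPi, pr$S, pr$U)
  edges <- engine$edges
  ## iterate edges in preorder (reverse postorder)
  for (i in rev(seq_len(nrow(edges)))) {
    p <- edges$parent[i]; c <- edges$child[i]
    sibs <- which(edges$parent == p)
    excl <- D[[p]]
    for (j in sibs) {
      if (j == i) next
      excl <- excl * (engine$P[[j]] %*% pr$F[[edges$child[j]]])
    }
    Dc <- crossprod(engine$P[[i]], excl)
    mx <- apply(Dc, 2L, max)
    mx[mx <= 0] <- 1
    D[[c]] <- sweep(Dc, 2L, mx, "/")
  }
  D
}

## ---- public single-column interfaces ---------------------------------------

## Normalize a user column specification to the leaves x 1 tuple matrix.
colTupleMatrix <- function(col, engine) {
  if (is.list(col)) col <- vapply(col, paste, character(1), collapse = "")
  if (is.null(names(col))) stop("column tuples must be named by leaf",
                                call. = FALSE)
  matrix(col, ncol = 1L, dimnames = list(names(col), NULL))
}

#' Felsenstein pruning likelihood of one column tuple
#'
#' Sums over all ancestral state assignments: the root state is drawn from
#' the chain's initial distribution, each branch contributes its transition
#' probability exp(Qt) (with hybrid-chain components resolved per branch by
#' the child node's label), and each leaf contributes an indicator over the
#' states compatible with its observed tokens.  Wildcards and gaps are
#' missing data: their indicator is 1 for every state.
#'
#' @param col named character vector (leaf -> observed token tuple, e.g.
#'   \code{c(human = "a", mouse = "c")}; arity-3 tuples are 3-character
#'   strings).
#' @param chain a \code{\link{Chain}} or \code{\link{HybridChain}}.
#' @param tree a \code{\link{PhyloTree}} whose leaves cover the names of
#'   \code{col}.
#' @param params a \code{\link{ParamSet}} (defaults to the chain's seeds).
#' @return the column probability.
#' @export
felsensteinLikelihood <- function(col, chain, tree, params = NULL) {
  if (is.null(params))
    params <- if (is(chain, "HybridChain")) chain@default@params else
      chain@params
  engine <- chainEngine(chain, tree, params)
  pr <- pruneColumns(engine, colTupleMatrix(col, engine))
  exp(pr$loglik[1L])
}

#' Marginal ancestral state posterior at a node
#'
#' Posterior distribution over chain states at one tree node given a single
#' observed column, by the inside-outside (up-down) recursion on the tree.
#' The most probable single state is the argmax of this distribution.
#'
#' @inheritParams felsensteinLikelihood
#' @param node label of the queried node (leaf or internal).
#' @return named numeric posterior over states (sums to 1).
#' @export
ancestralMarginal <- function(col, chain, tree, params = NULL, node) {
  if (is.null(params))
    params <- if (is(chain, "HybridChain")) chain@default@params else
      chain@params
  engine <- chainEngine(chain, tree, params)
  i <- nodeIndexOf(tree, node)
  pr <- pruneColumns(engine, colTupleMatrix(col, engine))
  D <- outsideColumns(engine, pr)
  post <- D[[i]][, 1L] * pr$F[[i]][, 1L]
  s <- sum(post)
  if (s <= 0) stop("zero-probability column; no posterior defined",
                   call. = FALSE)
  setNames(post / s, engine$states)
}

#' @describeIn ancestralMarginal the single most probable state (the argmax
#'   of the marginal posterior).
#' @export
ancestralArgmax <- function(col, chain, tree, params = NULL, node) {
  post <- ancestralMarginal(col, chain, tree, params, node)
  names(post)[which.max(post)]
}
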