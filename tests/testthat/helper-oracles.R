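# Independent brute-force oracles: exhaustive enumeration over ancestral
# state assignments, HMM state paths, and SCFG parses.  These deliberately
# avoid the package's dynamic-programming code paths: internal-node states
# are enumerated explicitly, leaf states are summed directly against their
# observation indicators.

# Branch matrices, observation indicators and the root distribution for a
# (possibly hybrid) chain on a tree.
.oracleSetup <- function(chain, tree, params, col) {
  if (is.null(params))
    params <- if (is(chain, "HybridChain")) chain@default@params else
      chain@params
  tmpl <- if (is(chain, "HybridChain")) chain@default else chain
  phy <- tree@phylo
  labs <- c(phy$tip.label, phy$node.label)
  S <- nStates(tmpl)
  P <- vector("list", nrow(phy$edge))
  for (i in seq_len(nrow(phy$edge))) {
    comp <- if (is(chain, "HybridChain")) {
      lab <- labs[phy$edge[i, 2L]]
      if (lab %in% names(chain@components)) chain@components[[lab]]
      else chain@default
    } else chain
    P[[i]] <- matrixExponential(instantiateMatrix(comp, params),
                                phy$edge.length[i])
  }
  ind <- matrix(1, length(labs), S)
  for (leaf in names(col)) {
    li <- match(leaf, labs)
    chars <- strsplit(col[[leaf]], "")[[1]]
    v <- rep(1, S)
    for (p in seq_along(chars)) {
      ch <- chars[p]
      if (ch %in% tmpl@alphabet@tokens)
        v <- v * as.numeric(tmpl@stateTokens[, p] == ch)
    }
    ind[li, ] <- v
  }
  list(phy = phy, labs = labs, S = S, P = P, ind = ind,
       pi = instantiateMatrix(tmpl, params)@pi,
       ntip = length(phy$tip.label))
}

# Sum over all internal-node state assignments; an optional clamp restricts
# one node (internal or leaf) to a single state.
.oracleLik <- function(su, clampNode = NA, clampState = NA) {
  phy <- su$phy
  internals <- su$ntip + seq_len(phy$Nnode)
  grid <- do.call(expand.grid, rep(list(seq_len(su$S)), length(internals)))
  root <- su$ntip + 1L
  leafEdges <- which(phy$edge[, 2L] <= su$ntip)
  intEdges <- setdiff(seq_len(nrow(phy$edge)), leafEdges)
  total <- 0
  for (g in seq_len(nrow(grid))) {
    st <- integer(length(su$labs))
    st[internals] <- as.integer(grid[g, ])
    if (!is.na(clampNode) && clampNode > su$ntip &&
        st[clampNode] != clampState) next
    w <- su$pi[st[root]] * su$ind[root, st[root]]
    for (i in intEdges) {
      p <- phy$edge[i, 1L]; c <- phy$edge[i, 2L]
      w <- w * su$P[[i]][st[p], st[c]] * su$ind[c, st[c]]
    }
    if (w == 0) next
    for (i in leafEdges) {
      p <- phy$edge[i, 1L]; c <- phy$edge[i, 2L]
      v <- su$ind[c, ]
      if (!is.na(clampNode) && clampNode == c) {
        keep <- numeric(su$S); keep[clampState] <- 1
        v <- v * keep
      }
      w <- w * sum(su$P[[i]][st[p], ] * v)
      if (w == 0) break
    }
    total <- total + w
  }
  total
}

bruteForceColumnLik <- function(chain, tree, params = NULL, col) {
  .oracleLik(.oracleSetup(chain, tree, params, col))
}

# Bayes-rule posterior over states at one node, by clamped enumeration.
bruteForceAncestral <- function(chain, tree, params = NULL, col, node) {
  su <- .oracleSetup(chain, tree, params, col)
  ni <- match(node, su$labs)
  post <- vapply(seq_len(su$S), function(s) .oracleLik(su, ni, s),
                 numeric(1))
  post / sum(post)
}

# Sum / max over all K^L state paths of a one-column-per-state HMM, using
# single-column likelihoods as emission terms.
enumerateHmmPaths <- function(states, start, A, end, emis, L,
                              what = c("sum", "max")) {
  what <- match.arg(what)
  K <- length(states)
  paths <- do.call(expand.grid, rep(list(seq_len(K)), L))
  best <- -Inf; total <- 0; bestPath <- NULL
  for (p in seq_len(nrow(paths))) {
    st <- as.integer(paths[p, ])
    w <- start[st[1L]] * emis[st[1L], 1L]
    if (L > 1L) for (i in 2:L)
      w <- w * A[st[i - 1L], st[i]] * emis[st[i], i]
    w <- w * end[st[L]]
    total <- total + w
    if (w > best) { best <- w; bestPath <- st }
  }
  if (what == "sum") unname(total) else
    list(score = unname(best), path = bestPath)
}

# Exhaustive SCFG parse enumeration over grammar rule records, mirroring
# the post-emission semantics but written as a direct recursion.
enumerateScfg <- function(g, rows, tree, params = g@params,
                          what = c("sum", "max")) {
  what <- match.arg(what)
  L <- ncol(rows)
  emits <- list()
  for (r in g@rules) if (r$kind == "emission")
    emits[[r$lhs]] <- c(emits[[r$lhs]], list(r))
  hasOwn <- function(nt) any(vapply(g@rules, function(q)
    q$kind %in% c("transition", "end", "bifurcation") && q$lhs == nt,
    logical(1)))
  rulesOf <- function(sym) {
    # post:X pseudo-symbols carry X's continuation rules
    if (startsWith(sym, "post:")) {
      owner <- substring(sym, 6L)
      star <- emits[[owner]][[1L]]$nxt
      out <- list()
      for (r in g@rules) {
        if (r$kind == "emission") next
        if (r$lhs == star) {
          if (hasOwn(owner) && r$kind %in% c("transition", "return") &&
              identical(r$to, owner) && identical(r$prob, "1")) next
          out <- c(out, list(r))
        } else if (r$lhs == owner) out <- c(out, list(r))
      }
      return(out)
    }
    if (sym %in% names(emits)) return(emits[[sym]])
    Filter(function(r) r$kind != "emission" && r$lhs == sym, g@rules)
  }
  emLik <- function(chain, cols) {
    tuple <- apply(rows[, cols, drop = FALSE], 1L, paste, collapse = "")
    felsensteinLikelihood(tuple, g@chains[[chain]], tree, params)
  }
  combine <- function(a, b) if (what == "sum") a + b else max(a, b)
  score <- function(sym, i, j) {
    acc <- 0
    for (r in rulesOf(sym)) {
      p <- phygram:::evalExpr(r$prob, params)
      if (r$kind == "end") {
        if (i == j) acc <- combine(acc, p)
      } else if (r$kind %in% c("transition", "return")) {
        acc <- combine(acc, p * score(r$to, i, j))
      } else if (r$kind == "bifurcation") {
        if (j - i >= 2L) for (k in (i + 1L):(j - 1L))
          acc <- combine(acc, p * score(r$to[1L], i, k) *
                           score(r$to[2L], k, j))
      } else if (r$kind == "emission") {
        a <- r$left + r$right
        if (j - i < a) next
        cols <- c(if (r$left) (i + 1L):(i + r$left),
                  if (r$right) (j - r$right + 1L):j)
        acc <- combine(acc, emLik(r$chain, cols) *
                         score(paste0("post:", r$lhs),
                               i + r$left, j - r$right))
      }
    }
    acc
  }
  score(g@start, 0L, L)
}
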