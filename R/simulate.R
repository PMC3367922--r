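## Generative sampling: draw a parse from the grammar, sample root token
## tuples from the chain initial distributions, evolve them down the tree,
## and emit a Stockholm alignment annotated with the ground-truth parse.

## Sample one derivation tree from a symbol, locally normalizing rule
## weights (end weights included).  Used directly for phylo-SCFGs.
sampleDerivation <- function(scfg, sym, forbidEnd = FALSE,
                             maxSteps = 1e6) {
  steps <- 0L
  rec <- function(s) {
    steps <<- steps + 1L
    if (steps > maxSteps)
      stop("derivation did not terminate within ", maxSteps, " steps",
           call. = FALSE)
    ris <- which(vapply(scfg$rules, function(r) scfg$symId[r$lhs] == s,
                        logical(1)))
    w <- vapply(ris, function(ri) scfg$rules[[ri]]$p, numeric(1))
    if (!length(ris) || sum(w) <= 0)
      stop("zero-probability continuation at nonterminal ", scfg$syms[s],
           call. = FALSE)
    ri <- ris[sample.int(length(ris), 1L, prob = w)]
    r <- scfg$rules[[ri]]
    switch(r$kind,
      end = list(kind = "end"),
      transition = list(kind = "trans", inner = rec(scfg$symId[r$to[1L]])),
      bifurcation = list(kind = "bif",
                         left = rec(scfg$symId[r$to[1L]]),
                         right = rec(scfg$symId[r$to[2L]])),
      emission = list(kind = "emit", rule = r,
                      inner = rec(scfg$symId[r$nxt])))
  }
  rec(scfg$symId[sym])
}

derivLength <- function(node) {
  switch(node$kind,
    end = 0L,
    trans = derivLength(node$inner),
    bif = derivLength(node$left) + derivLength(node$right),
    emit = node$rule$left + node$rule$right + derivLength(node$inner))
}

derivEmissions <- function(node, i, j, acc = NULL) {
  if (is.null(acc)) acc <- new.env(parent = emptyenv())
  if (is.null(acc$rows)) acc$rows <- list()
  switch(node$kind,
    end = NULL,
    trans = derivEmissions(node$inner, i, j, acc),
    bif = {
      k <- i + derivLength(node$left)
      derivEmissions(node$left, i, k, acc)
      derivEmissions(node$right, k, j, acc)
    },
    emit = {
      r <- node$rule
      cols <- emissionCols(r, i, j)
      acc$rows[[length(acc$rows) + 1L]] <-
        list(nonterm = r$lhs, chain = r$chain, cols = cols)
      derivEmissions(node$inner, i + r$left, j - r$right, acc)
    })
  acc$rows
}

#' Sample a parse from a grammar
#'
#' Applies transformation rules from the start nonterminal until only
#' pseudoterminals remain, sampling each step from the locally normalized
#' rule weights.  For phylo-HMMs a fixed alignment length can be requested:
#' the state path is then conditioned on emitting exactly that many columns
#' (end weights are dropped until the target is reached); phylo-SCFGs use
#' rejection against a length window instead.
#'
#' @param g a validated \code{\link{Grammar}}.
#' @param length target number of columns (\code{NULL} = let end rules
#'   decide).
#' @param seed integer seed for reproducibility (\code{NULL} = leave the
#'   RNG state alone).
#' @param params parameter set (defaults to the grammar's).
#' @param maxAttempts rejection attempts for SCFG length conditioning.
#' @return list with \code{emissions} (list of emission instances with
#'   1-based column sets), \code{length}, and for HMM paths \code{states}
#'   (the nonterminal sequence).
#' @export
sampleParse <- function(g, length = NULL, seed = NULL, params = g@params,
                        maxAttempts = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  if (classifyGrammar(g) == "phylo-HMM") {
    hmm <- compileHMM(g, params)
    K <- base::length(hmm$states)
    pick <- function(w) {
      if (sum(w) <= 0) stop("zero-probability continuation", call. = FALSE)
      sample.int(base::length(w), 1L, prob = w)
    }
    emis <- list()
    states <- character(0)
    col <- 0L
    k <- pick(hmm$start)
    repeat {
      a <- unname(hmm$arity[k])
      if (!is.null(length) && col + a > length)
        stop("cannot reach requested length with state arities",
             call. = FALSE)
      emis[[base::length(emis) + 1L]] <-
        list(nonterm = hmm$states[k], chain = hmm$chainKey[k],
             cols = (col + 1L):(col + a))
      states <- c(states, hmm$states[k])
      col <- col + a
      if (is.null(length)) {
        w <- c(hmm$A[k, ], hmm$end[k])
        nxt <- pick(w)
        if (nxt > K) break
        k <- nxt
      } else {
        if (col == length) break
        k <- pick(hmm$A[k, ])
      }
    }
    return(list(emissions = emis, length = col, states = states))
  }
  scfg <- compileSCFG(g, params)
  for (att in seq_len(maxAttempts)) {
    node <- sampleDerivation(scfg, g@start)
    L <- derivLength(node)
    if (is.null(length) || L == length) {
      return(list(emissions = derivEmissions(node, 0L, L),
                  length = L, states = NULL))
    }
  }
  stop("could not sample a parse of length ", length, " in ", maxAttempts,
       " attempts", call. = FALSE)
}

## Sample states down the tree for one emission instance; returns the state
## index at every node.
sampleTreeStates <- function(engine, rootState = NULL) {
  S <- base::length(engine$states)
  nn <- engine$ntip + engine$tree@phylo$Nnode
  st <- integer(nn)
  st[engine$root] <- if (is.null(rootState))
    sample.int(S, 1L, prob = engine$rootPi) else rootState
  edges <- engine$edges
  for (i in rev(seq_len(nrow(edges)))) {   # parents before children
    p <- edges$parent[i]; c <- edges$child[i]
    st[c] <- sample.int(S, 1L, prob = engine$P[[i]][st[p], ])
  }
  st
}

#' Evolve a sampled parse into an annotated alignment
#'
#' For each emission slot, samples a root tuple from the chain's initial
#' distribution and evolves it down the tree (children sampled from
#' exp(Qt) rows per branch, hybrid components resolved per branch), writing
#' leaves as alignment rows, the true parse as a \code{#=GC} row, and
#' hidden-class labels as \code{#=GR} rows.
#'
#' @param parse result of \code{\link{sampleParse}}.
#' @param g the generating \code{\link{Grammar}}.
#' @param tree a \code{\link{PhyloTree}}.
#' @param seed integer seed (\code{NULL} = leave the RNG state alone).
#' @param params parameter set.
#' @param gcRow name of the truth \code{#=GC} row.
#' @return a \code{\link{StockholmAlignment}} with truth annotations; the
#'   attribute \code{"truth"} carries the per-column generating nonterminal.
#' @export
evolveColumns <- function(parse, g, tree, seed = NULL, params = g@params,
                          gcRow = "STATE") {
  if (!is.null(seed)) set.seed(seed)
  leaves <- treeLeafLabels(tree)
  L <- parse$length
  mat <- matrix("-", base::length(leaves), L,
                dimnames = list(leaves, NULL))
  truth <- rep(NA_character_, L)
  labelOf <- function(nt) {
    hit <- match(nt, g@annotations$nonterm)
    if (!is.na(hit)) g@annotations$label[hit] else substr(nt, 1L, 1L)
  }
  classRows <- list()
  engines <- list()
  for (e in parse$emissions) {
    key <- e$chain
    if (is.null(engines[[key]]))
      engines[[key]] <- chainEngine(g@chains[[key]], tree, params)
    engine <- engines[[key]]
    ch <- engine$template
    st <- sampleTreeStates(engine)
    for (leaf in leaves) {
      li <- nodeIndexOf(tree, leaf)
      toks <- ch@stateTokens[st[li], ]
      mat[leaf, e$cols] <- toks
      if (base::length(ch@classLabels)) {
        if (is.null(classRows[[leaf]]))
          classRows[[leaf]] <- rep(".", L)
        classRows[[leaf]][e$cols] <- ch@stateClass[st[li]]
      }
    }
    truth[e$cols] <- e$nonterm
  }
  seqs <- apply(mat, 1L, paste, collapse = "")
  gc <- setNames(paste(vapply(truth, function(nt)
    if (is.na(nt)) "." else labelOf(nt), character(1)), collapse = ""),
    gcRow)
  gr <- lapply(classRows, function(v)
    c(CLASS = paste(v, collapse = "")))
  aln <- stockholmAlignment(seqs, gc = gc, gr = gr, tree = tree)
  attr(aln, "truth") <- truth
  aln
}

#' @describeIn evolveColumns one-call simulation: sample a parse and evolve
#'   it.
#' @inheritParams sampleParse
#' @param length target alignment length.
#' @export
simulateAlignment <- function(g, tree, length = NULL, seed = NULL,
                              params = g@params) {
  if (!is.null(seed)) set.seed(seed)
  parse <- sampleParse(g, length = length, params = params)
  evolveColumns(parse, g, tree, params = params)
}

#' Event-path sampling along one branch
#'
#' Gillespie simulation of the substitution process: starting from a
#' stationary draw, waits are exponential with rate -Q[i,i] and jumps are
#' chosen by the off-diagonal rates.  Used to check expected event counts
#' against the generator's closed-form rate.
#'
#' @param chain a \code{\link{Chain}}.
#' @param t branch length.
#' @param n number of independent replicate sites.
#' @param seed integer seed.
#' @param params parameter set.
#' @return numeric vector of event counts, one per site.
#' @export
samplePathCounts <- function(chain, t, n = 1000L, seed = NULL,
                             params = chain@params) {
  if (!is.null(seed)) set.seed(seed)
  rm <- instantiateMatrix(chain, params)
  Q <- rm@Q
  S <- nrow(Q)
  counts <- integer(n)
  for (r in seq_len(n)) {
    s <- sample.int(S, 1L, prob = rm@pi)
    tt <- 0; k <- 0L
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      tt <- tt + stats::rexp(1L, rate)
      if (tt > t) break
      w <- Q[s, ]; w[s] <- 0
      s <- sample.int(S, 1L, prob = w)
      k <- k + 1L
    }
    counts[r] <- k
  }
  counts
}
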