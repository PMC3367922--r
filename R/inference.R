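## Grammar-level dynamic programming: compilation of the rule set, the
## forward-backward specialization for phylo-HMMs, the span-based inside /
## outside / CYK recursions for phylo-SCFGs (with pairing-distance banding),
## and posterior annotation of alignments.
##
## Rule semantics: an emitting nonterminal emits its column tuple with
## probability one upon entry; its probabilistic transitions apply after the
## emission.  Both written dialects are accepted — transitions from the
## unstarred name (with a trivial star -> name return rule), or transitions
## from the starred continuation — and resolve to the same model.

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## ---- alignment access ------------------------------------------------------

## Named character vector of rows -> leaves x L character matrix.
asRowMatrix <- function(aln) {
  if (is(aln, "StockholmAlignment")) aln <- alignmentRows(aln)
  if (is.matrix(aln)) return(aln)
  if (!is.character(aln) || is.null(names(aln)))
    stop("alignment must be a StockholmAlignment or named character vector",
         call. = FALSE)
  if (length(unique(nchar(aln))) != 1L)
    stop("alignment rows have unequal lengths", call. = FALSE)
  m <- do.call(rbind, strsplit(tolower(aln), ""))
  rownames(m) <- names(aln)
  m
}

## ---- compilation -----------------------------------------------------------

## Post-emission rule set of an emitting nonterminal: rules from the starred
## continuation (minus the trivial return to self) plus non-emission rules
## from the unstarred name.
postEmissionRules <- function(g, lhs, star) {
  ownRules <- any(vapply(g@rules, function(r)
    r$kind %in% c("transition", "end", "bifurcation") && r$lhs == lhs,
    logical(1)))
  idx <- integer(0)
  for (i in seq_along(g@rules)) {
    r <- g@rules[[i]]
    if (r$kind == "emission") next
    if (r$lhs == star) {
      ## A star -> owner rule with probability 1 is structural sugar when
      ## the owner carries its own continuation rules; otherwise it is a
      ## genuine re-emission transition.
      if (ownRules && r$kind %in% c("transition", "return") &&
          identical(r$to, lhs) && identical(r$prob, "1")) next
      idx <- c(idx, i)
    } else if (r$lhs == lhs) idx <- c(idx, i)
  }
  idx
}

## Compile a phylo-HMM: states are the emitting nonterminals; start /
## transition / end weights collapse deterministic chains of non-emitting
## transitions.  Each effective weight keeps the list of (rule index, path
## weight) pairs behind it so EM can attribute expected usage to rules.
compileHMM <- function(g, params = g@params) {
  if (classifyGrammar(g) != "phylo-HMM")
    stop("grammar is a phylo-SCFG; the forward-backward recursion requires ",
         "a phylo-HMM", call. = FALSE)
  emits <- list()
  for (i in seq_along(g@rules)) {
    r <- g@rules[[i]]
    if (r$kind == "emission") {
      if (!is.null(emits[[r$lhs]]))
        stop("phylo-HMM state with multiple emission rules: ", r$lhs,
             call. = FALSE)
      emits[[r$lhs]] <- r
    }
  }
  states <- names(emits)
  K <- length(states)
  if (K == 0L) stop("grammar has no emitting nonterminals", call. = FALSE)
  ruleProb <- function(i) evalExpr(g@rules[[i]]$prob, params)
  ## Paths from a list of outgoing rule indices to emitting states / end.
  ## Returns list of list(to = state or "", w = weight, rules = indices).
  collapse <- function(ruleIdx, seen) {
    out <- list()
    for (i in ruleIdx) {
      r <- g@rules[[i]]
      w <- ruleProb(i)
      if (r$kind == "end") {
        out[[length(out) + 1L]] <- list(to = "", w = w, rules = i)
      } else if (r$kind %in% c("transition", "return")) {
        tgt <- r$to
        if (tgt %in% states) {
          out[[length(out) + 1L]] <- list(to = tgt, w = w, rules = i)
        } else {
          if (tgt %in% seen)
            stop("cycle through non-emitting nonterminals at ", tgt,
                 call. = FALSE)
          sub <- collapse(which(vapply(g@rules, function(q)
            q$kind %in% c("transition", "return", "end") && q$lhs == tgt,
            logical(1))), c(seen, tgt))
          for (s in sub)
            out[[length(out) + 1L]] <- list(to = s$to, w = w * s$w,
                                            rules = c(i, s$rules))
        }
      }
    }
    out
  }
  fromRules <- function(lhs) which(vapply(g@rules, function(q)
    q$kind %in% c("transition", "return", "end") && q$lhs == lhs,
    logical(1)))
  startPaths <- if (g@start %in% states)
    list(list(to = g@start, w = 1, rules = integer(0)))
  else collapse(fromRules(g@start), g@start)
  A <- matrix(0, K, K, dimnames = list(states, states))
  endW <- setNames(numeric(K), states)
  startW <- setNames(numeric(K), states)
  paths <- list(start = startPaths, trans = list())
  for (p in startPaths)
    if (nzchar(p$to)) startW[p$to] <- startW[p$to] + p$w
  for (k in states) {
    pk <- collapse(postEmissionRules(g, k, emits[[k]]$nxt), k)
    paths$trans[[k]] <- pk
    for (p in pk) {
      if (nzchar(p$to)) A[k, p$to] <- A[k, p$to] + p$w
      else endW[k] <- endW[k] + p$w
    }
  }
  arity <- vapply(states, function(k) {
    ch <- g@chains[[emits[[k]]$chain]]
    chainArity(ch)
  }, integer(1))
  list(states = states, emits = emits, A = A, start = startW, end = endW,
       arity = arity, paths = paths,
       chainKey = vapply(states, function(k) emits[[k]]$chain, character(1)))
}

## Per-state emission log-likelihoods at every feasible start column.
## Returns K x L matrix (NA where the tuple would overrun) plus, for EM, the
## per-chain tuple bookkeeping.
hmmEmissionLogliks <- function(g, hmm, rows, tree, params) {
  L <- ncol(rows)
  K <- length(hmm$states)
  E <- matrix(-Inf, K, L)
  book <- list()
  for (key in unique(hmm$chainKey)) {
    ks <- which(hmm$chainKey == key)
    a <- hmm$arity[ks[1L]]
    if (L < a) next
    starts <- seq_len(L - a + 1L)
    tuples <- matrix("", nrow(rows), length(starts),
                     dimnames = list(rownames(rows), NULL))
    for (s in seq_along(starts)) {
      cols <- starts[s]:(starts[s] + a - 1L)
      tuples[, s] <- apply(rows[, cols, drop = FALSE], 1L, paste,
                           collapse = "")
    }
    keys <- apply(tuples, 2L, paste, collapse = "\r")
    uniq <- !duplicated(keys)
    engine <- chainEngine(g@chains[[key]], tree, params)
    pr <- pruneColumns(engine, tuples[, uniq, drop = FALSE])
    ll <- pr$loglik[match(keys, keys[uniq])]
    for (k in ks) E[k, starts] <- ll
    book[[key]] <- list(engine = engine, pr = pr, uniq = which(uniq),
                        map = match(keys, keys[uniq]), starts = starts,
                        stateRows = ks)
  }
  list(E = E, book = book)
}

#' Forward-backward decoding of a phylo-HMM
#'
#' Computes the total log-likelihood of an alignment under a phylo-HMM
#' grammar and the per-column posterior of each emitting nonterminal.  End
#' weights are treated as unnormalized (the dynamic programming normalizes
#' globally).  States emitting wider tuples (e.g. codon triplets) advance by
#' their arity.
#'
#' @param g a phylo-HMM \code{\link{Grammar}}.
#' @param aln a \code{StockholmAlignment} or named character vector of rows.
#' @param tree a \code{\link{PhyloTree}} covering the rows.
#' @param params parameter set (defaults to the grammar's).
#' @return list with \code{loglik}, \code{posterior} (columns x states),
#'   and internal tables reused by training.
#' @export
forwardBackward <- function(g, aln, tree, params = g@params) {
  rows <- asRowMatrix(aln)
  hmm <- compileHMM(g, params)
  em <- hmmEmissionLogliks(g, hmm, rows, tree, params)
  E <- em$E
  K <- length(hmm$states)
  L <- ncol(rows)
  logA <- log(hmm$A); logS <- log(hmm$start); logEnd <- log(hmm$end)
  f <- matrix(-Inf, L + 1L, K)
  for (i in seq_len(L)) {
    for (k in seq_len(K)) {
      a <- hmm$arity[k]
      if (i < a) next
      e <- E[k, i - a + 1L]
      if (!is.finite(e)) next
      acc <- if (i == a) logS[k] else -Inf
      prev <- f[i - a + 1L, ] + logA[, k]
      acc <- logSumExp(c(acc, prev))
      f[i + 1L, k] <- acc + e
    }
  }
  total <- logSumExp(f[L + 1L, ] + logEnd)
  b <- matrix(-Inf, L + 1L, K)
  b[L + 1L, ] <- logEnd
  for (i in rev(seq_len(L))) {
    ## b[i, k]: generate columns i..L given the previous emission ended at
    ## column i-1 in state k
    for (k in seq_len(K)) {
      terms <- -Inf
      for (l in seq_len(K)) {
        a <- hmm$arity[l]
        if (i + a - 1L > L) next
        e <- E[l, i]
        if (!is.finite(e)) next
        terms <- logSumExp(c(terms, logA[k, l] + e + b[i + a, l]))
      }
      b[i, k] <- terms
    }
  }
  ## posterior of "state k's emission starts at column i"
  gammaStart <- matrix(0, L, K, dimnames = list(NULL, hmm$states))
  for (k in seq_len(K)) {
    a <- hmm$arity[k]
    for (i in seq_len(L - a + 1L)) {
      gammaStart[i, k] <- exp(f[i + a, k] + b[i + a, k] - total)
    }
  }
  ## per-column posterior (spread multi-column tuples over their columns)
  post <- matrix(0, L, K, dimnames = list(NULL, hmm$states))
  for (k in seq_len(K)) {
    a <- hmm$arity[k]
    for (off in seq_len(a) - 1L) {
      idx <- seq_len(L - a + 1L)
      post[idx + off, k] <- post[idx + off, k] + gammaStart[idx, k]
    }
  }
  list(loglik = total, posterior = post, gammaStart = gammaStart,
       f = f, b = b, hmm = hmm, em = em, rows = rows)
}

## Expected usage of every grammar rule plus expected transition-level
## counts, from the forward-backward tables.
hmmExpectedCounts <- function(fb) {
  hmm <- fb$hmm; E <- fb$em$E
  K <- length(hmm$states); L <- nrow(fb$posterior)
  total <- fb$loglik
  logA <- log(hmm$A); logS <- log(hmm$start); logEnd <- log(hmm$end)
  transCount <- matrix(0, K, K, dimnames = dimnames(hmm$A))
  for (k in seq_len(K)) for (l in seq_len(K)) {
    if (!is.finite(logA[k, l])) next
    a <- hmm$arity[l]
    acc <- 0
    for (i in seq_len(L)) {           # transition taken after column i
      if (i + a > L + 1L) next
      e <- E[l, i]
      if (!is.finite(e) || !is.finite(fb$f[i + 1L, k])) next
      acc <- acc + exp(fb$f[i + 1L, k] + logA[k, l] + e + fb$b[i + a, l] -
                       total)
    }
    transCount[k, l] <- acc
  }
  startCount <- setNames(numeric(K), hmm$states)
  endCount <- setNames(numeric(K), hmm$states)
  for (k in seq_len(K)) {
    a <- hmm$arity[k]
    if (is.finite(logS[k]) && a <= L && is.finite(E[k, 1L]))
      startCount[k] <- exp(logS[k] + E[k, 1L] + fb$b[1L + a, k] - total)
    if (is.finite(logEnd[k]))
      endCount[k] <- exp(fb$f[L + 1L, k] + logEnd[k] - total)
  }
  ## attribute to grammar rules through the collapsed paths
  ruleUsage <- numeric(0)
  addPath <- function(paths, weightByTarget) {
    ## weightByTarget: named list over targets ("" = end)
    for (z in seq_along(weightByTarget)) {
      tgt <- names(weightByTarget)[z]
      w <- weightByTarget[[z]]
      if (w <= 0) next
      sel <- Filter(function(p) identical(p$to, tgt), paths)
      tw <- sum(vapply(sel, function(p) p$w, numeric(1)))
      if (tw <= 0) next
      for (p in sel) {
        share <- w * p$w / tw
        for (ri in p$rules) {
          key <- as.character(ri)
          ruleUsage[key] <<- (if (is.na(ruleUsage[key])) 0
                              else ruleUsage[key]) + share
        }
      }
    }
  }
  sw <- startCount; names(sw) <- hmm$states
  addPath(fb$hmm$paths$start, as.list(sw))
  for (k in seq_along(hmm$states)) {
    tgts <- c(as.list(setNames(transCount[k, ], hmm$states)),
              stats::setNames(list(endCount[k]), ""))
    addPath(fb$hmm$paths$trans[[hmm$states[k]]], tgts)
  }
  list(trans = transCount, start = startCount, end = endCount,
       ruleUsage = ruleUsage)
}

## ---- SCFG inside / outside / CYK -------------------------------------------

## Internal symbol table: each emitting nonterminal A gets a continuation
## symbol post:A carrying its post-emission rules; other symbols keep their
## rules.  Rules are re-expressed over the symbol set.
compileSCFG <- function(g, params = g@params) {
  emits <- list()
  for (i in seq_along(g@rules)) {
    r <- g@rules[[i]]
    if (r$kind == "emission") emits[[r$lhs]] <- c(emits[[r$lhs]], list(r))
  }
  syms <- unique(c(g@start, unlist(lapply(g@rules, function(r)
    c(r$lhs, if (r$kind %in% c("transition", "return", "bifurcation"))
        r$to)))))
  post <- paste0("post:", names(emits))
  names(post) <- names(emits)
  allSyms <- c(syms, unname(post))
  rules <- list()
  addRule <- function(lst) rules[[length(rules) + 1L]] <<- lst
  for (A in names(emits))
    for (r in emits[[A]])
      addRule(list(kind = "emission", lhs = A, chain = r$chain,
                   left = r$left, right = r$right, nxt = unname(post[A]),
                   p = 1, idx = NA_integer_))
  for (i in seq_along(g@rules)) {
    r <- g@rules[[i]]
    if (r$kind == "emission") next
    lhs <- r$lhs
    ## attach post-emission rules to post:A; drop trivial return sugar
    if (lhs %in% names(emits)) lhs <- unname(post[lhs])
    isStarOf <- vapply(emits, function(rs) rs[[1L]]$nxt, character(1))
    if (r$lhs %in% isStarOf) {
      owner <- names(isStarOf)[match(r$lhs, isStarOf)]
      ownerHasRules <- any(vapply(g@rules, function(q)
        q$kind %in% c("transition", "end", "bifurcation") &&
          q$lhs == owner, logical(1)))
      if (ownerHasRules && r$kind %in% c("transition", "return") &&
          identical(r$to, owner) && identical(r$prob, "1")) next
      lhs <- unname(post[owner])
    }
    p <- evalExpr(r$prob, params)
    tgt <- if (r$kind == "end") character(0) else r$to
    addRule(list(kind = if (r$kind == "return") "transition" else r$kind,
                 lhs = lhs, to = tgt, p = p, idx = i))
  }
  ## same-span dependency order: A -> B via transitions
  symId <- seq_along(allSyms); names(symId) <- allSyms
  dep <- matrix(FALSE, length(allSyms), length(allSyms))
  for (r in rules)
    if (r$kind == "transition")
      dep[symId[r$lhs], symId[r$to[1L]]] <- TRUE
  order <- integer(0)
  left <- seq_along(allSyms)
  while (length(left)) {
    free <- left[vapply(left, function(s) !any(dep[s, left]), logical(1))]
    if (!length(free))
      stop("transition cycle among nonterminals; not supported",
           call. = FALSE)
    order <- c(order, free)
    left <- setdiff(left, free)
  }
  list(syms = allSyms, symId = symId, rules = rules, order = order,
       start = g@start)
}

## Emission log-likelihood lookup for the SCFG DP: memoized per chain on the
## exact column sets needed.
scfgEmissionTables <- function(g, scfg, rows, tree, params, band) {
  L <- ncol(rows)
  tables <- list()
  for (r in scfg$rules) {
    if (r$kind != "emission") next
    key <- paste0(r$chain, ":", r$left, ":", r$right)
    if (!is.null(tables[[key]])) next
    l <- r$left; rt <- r$right; a <- l + rt
    if (l > 0L && rt > 0L) {
      ## two-sided (paired) emission: one column set per (i, j) span,
      ## respecting the pairing band
      colSets <- list()
      maxW <- if (is.null(band)) L else min(L, band + 1L)
      for (i in 0:(L - a)) for (j in seq(i + a, min(L, i + maxW))) {
        colSets[[length(colSets) + 1L]] <- c((i + 1L):(i + l),
                                             (j - rt + 1L):j)
      }
    } else {
      ## one-sided emission: contiguous blocks of `a` columns
      if (L < a) { tables[[key]] <- new.env(); next }
      colSets <- lapply(seq_len(L - a + 1L), function(s) s:(s + a - 1L))
    }
    if (!length(colSets)) { tables[[key]] <- new.env(); next }
    keys <- vapply(colSets, paste, character(1), collapse = ",")
    uniq <- !duplicated(keys)
    colSets <- colSets[uniq]; keys <- keys[uniq]
    tuples <- matrix("", nrow(rows), length(colSets),
                     dimnames = list(rownames(rows), NULL))
    for (s in seq_along(colSets))
      tuples[, s] <- apply(rows[, colSets[[s]], drop = FALSE], 1L, paste,
                           collapse = "")
    engine <- chainEngine(g@chains[[r$chain]], tree, params)
    pr <- pruneColumns(engine, tuples)
    e <- new.env(parent = emptyenv())
    for (s in seq_along(keys)) e[[keys[s]]] <- pr$loglik[s]
    attr(e, "engine") <- engine
    attr(e, "pr") <- pr
    attr(e, "keys") <- keys
    tables[[key]] <- e
  }
  tables
}

emissionCols <- function(r, i, j) {
  c(if (r$left) (i + 1L):(i + r$left),
    if (r$right) (j - r$right + 1L):j)
}

## The span DP.  mode "sum" -> inside; mode "max" -> CYK with backpointers.
scfgInside <- function(g, aln, tree, params = g@params, band = NULL,
                       mode = c("sum", "max")) {
  mode <- match.arg(mode)
  rows <- asRowMatrix(aln)
  L <- ncol(rows)
  scfg <- compileSCFG(g, params)
  tables <- scfgEmissionTables(g, scfg, rows, tree, params, band)
  nS <- length(scfg$syms)
  beta <- array(-Inf, dim = c(nS, L + 1L, L + 1L))
  bp <- if (mode == "max") vector("list", nS * (L + 1L) * (L + 1L)) else NULL
  bpIdx <- function(s, i, j) ((j) * (L + 1L) + i) * nS + s
  logp <- function(r) if (r$p > 0) log(r$p) else -Inf
  rulesBySym <- split(seq_along(scfg$rules),
                      vapply(scfg$rules, function(r) scfg$symId[r$lhs],
                             integer(1)))
  for (w in 0:L) for (i in 0:(L - w)) {
    j <- i + w
    for (s in scfg$order) {
      ris <- rulesBySym[[as.character(s)]]
      if (is.null(ris)) next
      vals <- numeric(0)
      whys <- list()
      for (ri in ris) {
        r <- scfg$rules[[ri]]
        if (r$kind == "end") {
          if (w == 0L) { vals <- c(vals, logp(r)); whys <- c(whys, list(list(rule = ri))) }
        } else if (r$kind == "transition") {
          v <- logp(r) + beta[scfg$symId[r$to[1L]], i + 1L, j + 1L]
          vals <- c(vals, v); whys <- c(whys, list(list(rule = ri)))
        } else if (r$kind == "bifurcation") {
          if (w >= 2L) for (k in (i + 1L):(j - 1L)) {
            v <- logp(r) + beta[scfg$symId[r$to[1L]], i + 1L, k + 1L] +
              beta[scfg$symId[r$to[2L]], k + 1L, j + 1L]
            vals <- c(vals, v); whys <- c(whys, list(list(rule = ri, k = k)))
          }
        } else if (r$kind == "emission") {
          a <- r$left + r$right
          if (w < a) next
          if (r$left > 0L && r$right > 0L && !is.null(band) &&
              (j - i - 1L) > band) next
          key <- paste0(r$chain, ":", r$left, ":", r$right)
          ck <- paste(emissionCols(r, i, j), collapse = ",")
          e <- tables[[key]][[ck]]
          if (is.null(e)) next
          v <- e + beta[scfg$symId[r$nxt], i + r$left + 1L,
                        j - r$right + 1L]
          vals <- c(vals, v); whys <- c(whys, list(list(rule = ri)))
        }
      }
      if (!length(vals)) next
      if (mode == "sum") {
        beta[s, i + 1L, j + 1L] <- logSumExp(vals)
      } else {
        best <- which.max(vals)
        beta[s, i + 1L, j + 1L] <- vals[best]
        if (is.finite(vals[best])) bp[[bpIdx(s, i, j)]] <- whys[[best]]
      }
    }
  }
  list(beta = beta, bp = bp, bpIdx = bpIdx, scfg = scfg, tables = tables,
       L = L, rows = rows,
       total = beta[scfg$symId[scfg$start], 1L, L + 1L])
}

#' Inside algorithm: total log-likelihood of an alignment under a grammar
#'
#' Span-based inside recursion over all parses, with emission terms from
#' Felsenstein pruning.  The optional band \code{N} excludes any paired
#' emission whose two columns are more than \code{N} positions apart,
#' bounding time and memory.
#'
#' @inheritParams forwardBackward
#' @param band maximal distance between paired columns (\code{NULL} =
#'   unbounded).
#' @return list with \code{loglik} and the DP table (\code{beta}).
#' @export
inside <- function(g, aln, tree, params = g@params, band = NULL) {
  ins <- scfgInside(g, aln, tree, params, band, mode = "sum")
  list(loglik = ins$total, beta = ins$beta, ins = ins)
}

#' CYK: the single most probable parse
#'
#' Max-product counterpart of \code{\link{inside}}: returns the best parse's
#' log score (always <= the inside total) and the per-column emitting
#' nonterminal labels derived from the traceback.  Ties break
#' deterministically toward the lowest-index rule.
#'
#' @inheritParams inside
#' @return list with \code{logscore}, \code{labels} (per-column emitting
#'   nonterminal, \code{NA} for unemitted columns) and \code{emissions}
#'   (data.frame of emission instances).
#' @export
cyk <- function(g, aln, tree, params = g@params, band = NULL) {
  ins <- scfgInside(g, aln, tree, params, band, mode = "max")
  L <- ins$L
  labels <- rep(NA_character_, L)
  emis <- list()
  if (is.finite(ins$total)) {
    stack <- list(list(s = ins$scfg$symId[ins$scfg$start], i = 0L, j = L))
    while (length(stack)) {
      fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      why <- ins$bp[[ins$bpIdx(fr$s, fr$i, fr$j)]]
      if (is.null(why)) next
      r <- ins$scfg$rules[[why$rule]]
      if (r$kind == "transition") {
        stack <- c(stack, list(list(s = ins$scfg$symId[r$to[1L]], i = fr$i,
                                    j = fr$j)))
      } else if (r$kind == "bifurcation") {
        stack <- c(stack,
                   list(list(s = ins$scfg$symId[r$to[1L]], i = fr$i,
                             j = why$k),
                        list(s = ins$scfg$symId[r$to[2L]], i = why$k,
                             j = fr$j)))
      } else if (r$kind == "emission") {
        cols <- emissionCols(r, fr$i, fr$j)
        labels[cols] <- r$lhs
        emis[[length(emis) + 1L]] <-
          data.frame(nonterm = r$lhs, chain = r$chain,
                     cols = I(list(cols)), i = fr$i, j = fr$j)
        stack <- c(stack, list(list(s = ins$scfg$symId[r$nxt],
                                    i = fr$i + r$left, j = fr$j - r$right)))
      }
    }
  }
  list(logscore = ins$total, labels = labels,
       emissions = if (length(emis)) do.call(rbind, emis) else NULL,
       ins = ins)
}

## Outside recursion + expected rule usages and emission posteriors.
scfgOutside <- function(ins) {
  scfg <- ins$scfg; L <- ins$L; beta <- ins$beta
  nS <- length(scfg$syms)
  alpha <- array(-Inf, dim = c(nS, L + 1L, L + 1L))
  alpha[scfg$symId[scfg$start], 1L, L + 1L] <- 0
  total <- ins$total
  ruleUsage <- numeric(0)
  emitPost <- list()   # per emission rule: data.frame i, j, weight
  addU <- function(ri, w) {
    r <- ins$scfg$rules[[ri]]
    if (!is.na(r$idx)) {
      key <- as.character(r$idx)
      ruleUsage[key] <<- (if (is.na(ruleUsage[key])) 0 else ruleUsage[key]) + w
    }
  }
  ## spans from widest down; within a span, symbols in dependency order
  for (w in L:0) for (i in 0:(L - w)) {
    j <- i + w
    for (s in rev(scfg$order)) {
      a0 <- alpha[s, i + 1L, j + 1L]
      if (!is.finite(a0)) next
      lhs <- scfg$syms[s]
      for (ri in seq_along(scfg$rules)) {
        r <- scfg$rules[[ri]]
        if (scfg$symId[r$lhs] != s) next
        if (r$kind == "end") {
          if (w == 0L && r$p > 0) addU(ri, exp(a0 + log(r$p) - total))
        } else if (r$kind == "transition") {
          if (r$p <= 0) next
          t <- scfg$symId[r$to[1L]]
          v <- a0 + log(r$p)
          alpha[t, i + 1L, j + 1L] <- logSumExp(c(alpha[t, i + 1L, j + 1L], v))
          bt <- beta[t, i + 1L, j + 1L]
          if (is.finite(bt)) addU(ri, exp(v + bt - total))
        } else if (r$kind == "bifurcation") {
          if (r$p <= 0 || w < 2L) next
          t1 <- scfg$symId[r$to[1L]]; t2 <- scfg$symId[r$to[2L]]
          for (k in (i + 1L):(j - 1L)) {
            b1 <- beta[t1, i + 1L, k + 1L]; b2 <- beta[t2, k + 1L, j + 1L]
            v1 <- a0 + log(r$p) + b2
            v2 <- a0 + log(r$p) + b1
            alpha[t1, i + 1L, k + 1L] <-
              logSumExp(c(alpha[t1, i + 1L, k + 1L], v1))
            alpha[t2, k + 1L, j + 1L] <-
              logSumExp(c(alpha[t2, k + 1L, j + 1L], v2))
            if (is.finite(b1) && is.finite(b2))
              addU(ri, exp(a0 + log(r$p) + b1 + b2 - total))
          }
        } else if (r$kind == "emission") {
          a <- r$left + r$right
          if (w < a) next
          key <- paste0(r$chain, ":", r$left, ":", r$right)
          ck <- paste(emissionCols(r, i, j), collapse = ",")
          e <- ins$tables[[key]][[ck]]
          if (is.null(e)) next
          t <- scfg$symId[r$nxt]
          ii <- i + r$left; jj <- j - r$right
          v <- a0 + e
          alpha[t, ii + 1L, jj + 1L] <-
            logSumExp(c(alpha[t, ii + 1L, jj + 1L], v))
          bt <- beta[t, ii + 1L, jj + 1L]
          if (is.finite(bt)) {
            wgt <- exp(a0 + e + bt - total)
            emitPost[[length(emitPost) + 1L]] <-
              data.frame(rule = ri, i = i, j = j, w = wgt)
          }
        }
      }
    }
  }
  list(alpha = alpha, ruleUsage = ruleUsage,
       emitPost = if (length(emitPost)) do.call(rbind, emitPost) else NULL)
}

#' @describeIn inside outside pass: per-column posterior probability that
#'   each emitting nonterminal generated the column, plus expected rule
#'   usages (list with \code{posterior}, \code{ruleUsage},
#'   \code{emitPost}).
#' @export
insideOutside <- function(g, aln, tree, params = g@params, band = NULL) {
  ins <- scfgInside(g, aln, tree, params, band, mode = "sum")
  out <- scfgOutside(ins)
  L <- ins$L
  ents <- unique(vapply(Filter(function(r) r$kind == "emission",
                               ins$scfg$rules), function(r) r$lhs,
                        character(1)))
  post <- matrix(0, L, length(ents), dimnames = list(NULL, ents))
  if (!is.null(out$emitPost)) {
    for (q in seq_len(nrow(out$emitPost))) {
      r <- ins$scfg$rules[[out$emitPost$rule[q]]]
      cols <- emissionCols(r, out$emitPost$i[q], out$emitPost$j[q])
      post[cols, r$lhs] <- post[cols, r$lhs] + out$emitPost$w[q]
    }
  }
  list(loglik = ins$total, posterior = post, ruleUsage = out$ruleUsage,
       emitPost = out$emitPost, ins = ins, out = out)
}
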