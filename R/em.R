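## EM training of grammar parameters: expected rule usages via
## forward-backward (phylo-HMMs) or inside-outside (phylo-SCFGs), expected
## substitution counts and wait times per chain via per-branch endpoint
## posteriors integrated along branches, then closed-form M-step updates
## for probability groups and tied rate parameters.

grammarLogLik <- function(g, alns, trees, params = g@params, band = NULL) {
  total <- 0
  for (q in seq_along(alns)) {
    total <- total + if (classifyGrammar(g) == "phylo-HMM")
      forwardBackward(g, alns[[q]], trees[[q]], params)$loglik
    else inside(g, alns[[q]], trees[[q]], params, band)$loglik
  }
  total
}

## E-step over one alignment: rule usages + per-parameter rate statistics.
emExpectations <- function(g, aln, tree, params, band) {
  rateAcc <- list()
  usage <- numeric(0)
  addUsage <- function(u) {
    for (key in names(u))
      usage[key] <<- (if (is.na(usage[key])) 0 else usage[key]) + u[key]
  }
  harvestChain <- function(engine, pr, w) {
    out <- outsideColumnsFull(engine, pr)
    cs <- chainSubstitutionCounts(engine, pr, out, w)
    for (k in names(cs$subs)) {
      ch <- engine$inst$chains[[k]]
      rateAcc <<- accumulateRateStats(ch, params, cs$subs[[k]],
                                      cs$wait[[k]], rateAcc)
    }
  }
  if (classifyGrammar(g) == "phylo-HMM") {
    fb <- forwardBackward(g, aln, tree, params)
    cnt <- hmmExpectedCounts(fb)
    addUsage(cnt$ruleUsage)
    for (key in names(fb$em$book)) {
      bk <- fb$em$book[[key]]
      pr <- bk$pr
      w <- numeric(pr$U)
      for (k in bk$stateRows) {
        gs <- fb$gammaStart[bk$starts, fb$hmm$states[k]]
        agg <- rowsum(gs, bk$map)
        w[as.integer(rownames(agg))] <- w[as.integer(rownames(agg))] +
          agg[, 1L]
      }
      harvestChain(bk$engine, pr, w)
    }
    loglik <- fb$loglik
  } else {
    io <- insideOutside(g, aln, tree, params, band)
    addUsage(io$ruleUsage)
    if (!is.null(io$emitPost)) {
      byRule <- split(seq_len(nrow(io$emitPost)), io$emitPost$rule)
      for (rn in names(byRule)) {
        r <- io$ins$scfg$rules[[as.integer(rn)]]
        key <- paste0(r$chain, ":", r$left, ":", r$right)
        tbl <- io$ins$tables[[key]]
        keys <- attr(tbl, "keys")
        pr <- attr(tbl, "pr")
        w <- setNames(numeric(length(keys)), keys)
        rowsIdx <- byRule[[rn]]
        cks <- vapply(rowsIdx, function(q) paste(
          emissionCols(r, io$emitPost$i[q], io$emitPost$j[q]),
          collapse = ","), character(1))
        for (z in seq_along(rowsIdx))
          w[cks[z]] <- w[cks[z]] + io$emitPost$w[rowsIdx[z]]
        harvestChain(attr(tbl, "engine"), pr, unname(w))
      }
    }
    loglik <- io$loglik
  }
  list(usage = usage, rateAcc = rateAcc, loglik = loglik)
}

## Combine expectations into new parameter values.
emMStep <- function(g, params, usage, rateAcc, fix, floor = 1e-6) {
  p <- params
  ## probability groups from rule usage counts
  for (gn in names(p@pgroups)) {
    grp <- p@pgroups[[gn]]
    cnt <- setNames(numeric(length(grp)), names(grp))
    any <- FALSE
    for (key in names(usage)) {
      r <- g@rules[[as.integer(key)]]
      if (r$kind == "emission") next
      for (f in r$prob)
        if (f %in% names(grp)) {
          cnt[f] <- cnt[f] + usage[key]
          any <- TRUE
        }
    }
    if (any && sum(cnt) > 0) {
      newGrp <- cnt / sum(cnt)
      keep <- names(grp) %in% fix
      if (any(keep)) newGrp[keep] <- grp[keep]
      newGrp <- newGrp / sum(newGrp)
      p@pgroups[[gn]] <- newGrp
    }
  }
  ## tied rate parameters (one coordinate sweep)
  for (pn in names(rateAcc)) {
    if (pn %in% fix || !(pn %in% names(p@rates))) next
    st <- rateAcc[[pn]]
    if (st["den"] > 0) {
      v <- st["num"] / st["den"]
      if (v < floor) {
        warning("rate parameter ", pn, " driven to 0; flooring at ", floor,
                call. = FALSE)
        v <- floor
      }
      p@rates[pn] <- unname(v)
    }
  }
  p
}

interpolateParams <- function(old, new, frac) {
  p <- new
  for (nm in names(p@rates))
    p@rates[nm] <- exp((1 - frac) * log(max(old@rates[nm], 1e-300)) +
                       frac * log(max(new@rates[nm], 1e-300)))
  for (gn in names(p@pgroups)) {
    mix <- (1 - frac) * old@pgroups[[gn]] + frac * new@pgroups[[gn]]
    p@pgroups[[gn]] <- mix / sum(mix)
  }
  p
}

#' Train grammar parameters by expectation-maximization
#'
#' E-step: expected rule usages from the grammar dynamic programming and
#' expected substitution counts / state wait times per chain from per-branch
#' endpoint posteriors integrated along each branch.  M-step: each
#' probability group is renormalized from its usage counts; each rate
#' parameter is updated from the tied sum of event counts over the matrix
#' entries whose expression contains it, divided by the correspondingly
#' weighted wait times (one coordinate sweep per iteration for products of
#' several parameters).  The log-likelihood trace is non-decreasing;
#' would-be decreasing steps are damped by backtracking and training stops
#' if no improving step exists.
#'
#' @param g a validated \code{\link{Grammar}}.
#' @param alignments list of alignments (or a single alignment).
#' @param trees list of matching \code{\link{PhyloTree}}s (or one tree).
#' @param maxIter maximum EM iterations.
#' @param tol relative log-likelihood improvement below which training
#'   stops.
#' @param fix parameter names to hold fixed.
#' @param band pairing band for phylo-SCFGs (see \code{\link{inside}}).
#' @param verbose print the trace while training.
#' @return list with \code{grammar} (trained), \code{trace} (log-likelihood
#'   per iteration, starting with the initial value), and \code{iterations}.
#' @export
emTrain <- function(g, alignments, trees, maxIter = 30L, tol = 1e-4,
                    fix = character(0), band = NULL, verbose = FALSE) {
  if (is(alignments, "StockholmAlignment") || is.character(alignments))
    alignments <- list(alignments)
  if (is(trees, "PhyloTree")) trees <- list(trees)
  if (length(alignments) == 0L) stop("no alignments to train on",
                                     call. = FALSE)
  if (length(trees) == 1L && length(alignments) > 1L)
    trees <- rep(trees, length(alignments))
  ncols <- vapply(alignments, function(a) ncol(asRowMatrix(a)), integer(1))
  if (sum(ncols) == 0L) stop("no data columns", call. = FALSE)
  params <- g@params
  cur <- grammarLogLik(g, alignments, trees, params, band)
  trace <- cur
  for (it in seq_len(maxIter)) {
    usage <- numeric(0); rateAcc <- list()
    for (q in seq_along(alignments)) {
      ex <- emExpectations(g, alignments[[q]], trees[[q]], params, band)
      for (key in names(ex$usage))
        usage[key] <- (if (is.na(usage[key])) 0 else usage[key]) +
          ex$usage[key]
      for (pn in names(ex$rateAcc)) {
        if (is.null(rateAcc[[pn]])) rateAcc[[pn]] <- c(num = 0, den = 0)
        rateAcc[[pn]] <- rateAcc[[pn]] + ex$rateAcc[[pn]]
      }
    }
    cand <- emMStep(g, params, usage, rateAcc, fix)
    newLL <- grammarLogLik(g, alignments, trees, cand, band)
    frac <- 1
    while (newLL < cur - 1e-6 * abs(cur) && frac > 1 / 64) {
      frac <- frac / 2
      cand <- interpolateParams(params, emMStep(g, params, usage, rateAcc,
                                                fix), frac)
      newLL <- grammarLogLik(g, alignments, trees, cand, band)
    }
    if (newLL < cur - 1e-6 * abs(cur)) break   # no improving step
    params <- cand
    improvement <- (newLL - cur) / max(1, abs(cur))
    cur <- newLL
    trace <- c(trace, cur)
    if (verbose) message(sprintf("EM iter %d: loglik %.6f", it, cur))
    if (improvement < tol) break
  }
  g@params <- params
  list(grammar = g, trace = trace, iterations = length(trace) - 1L)
}
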