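## Alignment annotation (best parse, posteriors, hidden classes, ancestral
## sequences) and the end-to-end processing pipeline behind the command
## line interface.

#' Parse annotation of an alignment
#'
#' The result of decoding an alignment under a grammar: per-column best
#' parse labels, per-column posteriors of each emitting nonterminal, GFF
#' features for maximal runs of each labeled nonterminal, WIG posterior
#' tracks, \code{#=GR} hidden-class rows, and (when requested) marginal
#' ancestral sequences per internal node.
#'
#' @slot labels per-column emitting nonterminal of the best parse.
#' @slot gc named character vector of \code{#=GC} annotation strings.
#' @slot posteriors columns x nonterminals posterior matrix.
#' @slot gff data.frame of GFF features.
#' @slot wig named list of per-column numeric tracks.
#' @slot gr per-sequence \code{#=GR} class annotation strings.
#' @slot ancestral named character vector of ancestral sequences (by
#'   internal node label).
#' @slot ancestralProb per-node numeric vectors: posterior of the chosen
#'   ancestral state per column.
#' @slot logscore best-parse log score.
#' @slot loglik total (summed over parses) log-likelihood.
#' @export
setClass("ParseAnnotation",
  representation(labels = "character", gc = "character",
                 posteriors = "matrix", gff = "data.frame", wig = "list",
                 gr = "list", ancestral = "character",
                 ancestralProb = "list", logscore = "numeric",
                 loglik = "numeric"))

setMethod("show", "ParseAnnotation", function(object) {
  cat("ParseAnnotation: ", length(object@labels), " columns, ",
      nrow(object@gff), " GFF features, log-likelihood ",
      format(object@loglik, digits = 6), " (best parse ",
      format(object@logscore, digits = 6), ")\n", sep = "")
})

## Viterbi decoding for phylo-HMMs (linear in alignment length).
hmmViterbi <- function(g, aln, tree, params = g@params) {
  rows <- asRowMatrix(aln)
  hmm <- compileHMM(g, params)
  em <- hmmEmissionLogliks(g, hmm, rows, tree, params)
  E <- em$E
  K <- length(hmm$states); L <- ncol(rows)
  logA <- log(hmm$A); logS <- log(hmm$start); logEnd <- log(hmm$end)
  v <- matrix(-Inf, L + 1L, K)
  ptr <- matrix(0L, L + 1L, K)
  for (i in seq_len(L)) for (k in seq_len(K)) {
    a <- hmm$arity[k]
    if (i < a) next
    e <- E[k, i - a + 1L]
    if (!is.finite(e)) next
    cand <- f0 <- if (i == a) logS[k] else -Inf
    best <- 0L
    prev <- v[i - a + 1L, ] + logA[, k]
    pb <- which.max(prev)
    if (length(prev) && prev[pb] > cand) { cand <- prev[pb]; best <- pb }
    v[i + 1L, k] <- cand + e
    ptr[i + 1L, k] <- best
  }
  fin <- v[L + 1L, ] + logEnd
  kk <- which.max(fin)
  labels <- rep(NA_character_, L)
  i <- L
  while (i > 0L) {
    a <- hmm$arity[kk]
    labels[(i - a + 1L):i] <- hmm$states[kk]
    prev <- ptr[i + 1L, kk]
    i <- i - a
    if (prev == 0L) break
    kk <- prev
  }
  list(labels = labels, logscore = max(fin))
}

## Per-sequence hidden-class #=GR strings for chains with latent classes,
## conditioned on the best parse: the leaf's class posterior given each
## column, maximized per column.
classAnnotationRows <- function(g, rows, tree, params, labels, emitsByNT) {
  gr <- list()
  leaves <- rownames(rows)
  for (key in names(g@chains)) {
    ch <- g@chains[[key]]
    tmpl <- if (is(ch, "HybridChain")) ch@default else ch
    if (!length(tmpl@classLabels)) next
    nts <- names(emitsByNT)[vapply(emitsByNT, function(x) x == key,
                                   logical(1))]
    cols <- which(labels %in% nts)
    if (!length(cols)) next
    a <- chainArity(ch)
    starts <- cols[seq(1L, length(cols), by = a)]
    tuples <- matrix("", length(leaves), length(starts),
                     dimnames = list(leaves, NULL))
    for (s in seq_along(starts))
      tuples[, s] <- apply(rows[, starts[s]:(starts[s] + a - 1L),
                                drop = FALSE], 1L, paste, collapse = "")
    engine <- chainEngine(ch, tree, params)
    pr <- pruneColumns(engine, tuples)
    out <- outsideColumnsFull(engine, pr)
    for (leaf in leaves) {
      li <- nodeIndexOf(tree, leaf)
      post <- out$D[[li]] * pr$F[[li]]
      if (is.null(gr[[leaf]])) gr[[leaf]] <- rep(".", length(labels))
      for (s in seq_along(starts)) {
        p <- post[, s]
        byClass <- rowsum(p, tmpl@stateClass)
        lab <- rownames(byClass)[which.max(byClass)]
        gr[[leaf]][starts[s]:(starts[s] + a - 1L)] <- lab
      }
    }
  }
  lapply(gr, function(v) c(CLASS = paste(v, collapse = "")))
}

## Marginal ancestral sequences per internal node, conditioned on the best
## parse (each column uses the chain of its best-parse nonterminal).
ancestralRows <- function(g, rows, tree, params, labels, emitsByNT) {
  phy <- tree@phylo
  internals <- phy$node.label
  L <- length(labels)
  anc <- matrix(".", length(internals), L,
                dimnames = list(internals, NULL))
  prob <- matrix(NA_real_, length(internals), L,
                 dimnames = list(internals, NULL))
  for (key in unique(unlist(emitsByNT))) {
    ch <- g@chains[[key]]
    tmpl <- if (is(ch, "HybridChain")) ch@default else ch
    nts <- names(emitsByNT)[vapply(emitsByNT, function(x) x == key,
                                   logical(1))]
    cols <- which(labels %in% nts)
    if (!length(cols)) next
    a <- chainArity(ch)
    starts <- cols[seq(1L, length(cols), by = a)]
    tuples <- matrix("", nrow(rows), length(starts),
                     dimnames = list(rownames(rows), NULL))
    for (s in seq_along(starts))
      tuples[, s] <- apply(rows[, starts[s]:(starts[s] + a - 1L),
                                drop = FALSE], 1L, paste, collapse = "")
    engine <- chainEngine(ch, tree, params)
    pr <- pruneColumns(engine, tuples)
    out <- outsideColumnsFull(engine, pr)
    for (nl in internals) {
      ni <- nodeIndexOf(tree, nl)
      post <- out$D[[ni]] * pr$F[[ni]]
      for (s in seq_along(starts)) {
        p <- post[, s] / sum(post[, s])
        best <- which.max(p)
        anc[nl, starts[s]:(starts[s] + a - 1L)] <-
          tmpl@stateTokens[best, ]
        prob[nl, starts[s]:(starts[s] + a - 1L)] <- p[best]
      }
    }
  }
  list(anc = apply(anc, 1L, paste, collapse = ""),
       prob = setNames(lapply(seq_len(nrow(prob)), function(i) prob[i, ]),
                       internals))
}

#' Annotate an alignment under a grammar
#'
#' Decodes the best parse (Viterbi for phylo-HMMs, CYK for phylo-SCFGs),
#' computes per-column nonterminal posteriors (forward-backward or
#' inside-outside), builds \code{#=GC} annotation rows from the grammar's
#' annotation directives, GFF features over maximal label runs, WIG
#' posterior tracks, \code{#=GR} hidden-class rows for latent-class chains,
#' and optionally marginal ancestral sequences conditioned on the best
#' parse.
#'
#' @inheritParams inside
#' @param ancestral reconstruct ancestral sequences (the \code{--ar}
#'   behavior; posteriors of the chosen states are kept too, the
#'   \code{--arpp} behavior).
#' @return a \code{\link{ParseAnnotation}}.
#' @export
annotateAlignment <- function(g, aln, tree, params = g@params, band = NULL,
                              ancestral = FALSE) {
  rows <- asRowMatrix(aln)
  L <- ncol(rows)
  isHmm <- classifyGrammar(g) == "phylo-HMM"
  if (isHmm) {
    fb <- forwardBackward(g, aln, tree, params)
    vt <- hmmViterbi(g, aln, tree, params)
    loglik <- fb$loglik; post <- fb$posterior
    labels <- vt$labels; logscore <- vt$logscore
  } else {
    io <- insideOutside(g, aln, tree, params, band)
    ck <- cyk(g, aln, tree, params, band)
    loglik <- io$loglik; post <- io$posterior
    labels <- ck$labels; logscore <- ck$logscore
  }
  emitsByNT <- list()
  for (r in g@rules)
    if (r$kind == "emission") emitsByNT[[r$lhs]] <- r$chain
  ## #=GC rows per annotation-directive row name
  ann <- g@annotations
  if (!nrow(ann))
    ann <- data.frame(nonterm = names(emitsByNT), row = "STATE",
                      label = substr(names(emitsByNT), 1L, 1L),
                      stringsAsFactors = FALSE)
  gc <- character(0)
  for (rw in unique(ann$row)) {
    sub <- ann[ann$row == rw, ]
    chars <- rep(".", L)
    for (q in seq_len(nrow(sub)))
      chars[!is.na(labels) & labels == sub$nonterm[q]] <- sub$label[q]
    gc[rw] <- paste(chars, collapse = "")
  }
  gff <- gffFeatures(labels, posterior = post)
  wig <- lapply(colnames(post), function(nt) post[, nt])
  names(wig) <- colnames(post)
  gr <- classAnnotationRows(g, rows, tree, params, labels, emitsByNT)
  anc <- character(0); ancp <- list()
  if (ancestral) {
    ar <- ancestralRows(g, rows, tree, params, labels, emitsByNT)
    anc <- ar$anc; ancp <- ar$prob
  }
  new("ParseAnnotation", labels = labels, gc = gc, posteriors = post,
      gff = gff, wig = wig, gr = gr, ancestral = anc,
      ancestralProb = ancp, logscore = logscore, loglik = loglik)
}

#' Run the full processing pipeline
#'
#' Mirrors the documented processing order: (1) the Stockholm file and the
#' grammar alphabet are parsed (macros may depend on them); (2) macros are
#' expanded; (3) a tree is estimated by neighbor-joining (from
#' JC69-corrected pairwise distances) when the input embeds none; (4)
#' parameters are trained if requested; (5) the alignment is annotated if
#' requested; (6) ancestral sequences are reconstructed if requested.  The
#' annotated alignment (tree embedded, ancestral rows appended as
#' additional sequences named by internal-node labels) goes to \code{out};
#' GFF/WIG go to standard output unless directed to files.
#'
#' @param grammarFile path to the grammar file.
#' @param alignFile path to the Stockholm alignment (multi-block supported).
#' @param out path for the annotated Stockholm output (\code{""} =
#'   standard output).
#' @param train estimate parameters before annotating.
#' @param trainOut path to write the trained grammar (implies
#'   \code{train}).
#' @param band maximal pairing distance (the \code{-l} limit;
#'   \code{NULL} = unbounded).
#' @param annotate decode and annotate the alignment.
#' @param ancestral append ancestral sequences.
#' @param gffFile,wigFile optional paths for GFF/WIG output.
#' @param seed integer seed (plumbing for stochastic extensions; inference
#'   itself is deterministic).
#' @param maxIter,tol EM controls (see \code{\link{emTrain}}).
#' @return invisibly, a list with per-block annotations and the (possibly
#'   trained) grammar.
#' @export
runPipeline <- function(grammarFile, alignFile, out = "", train = FALSE,
                        trainOut = NULL, band = NULL, annotate = TRUE,
                        ancestral = FALSE, gffFile = NULL, wigFile = NULL,
                        seed = NULL, maxIter = 30L, tol = 1e-4) {
  if (!file.exists(grammarFile)) stop("missing grammar file: ", grammarFile,
                                      call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  blocks <- readStockholm(alignFile)
  if (!length(blocks)) stop("no alignment blocks in ", alignFile,
                            call. = FALSE)
  if (!is.null(trainOut)) train <- TRUE
  trees <- lapply(blocks, function(b) {
    tr <- alignmentTree(b)
    if (is.null(tr)) tr <- neighborJoining(jcDistances(alignmentRows(b)))
    tr
  })
  ## grammar expanded in the context of the first block
  g <- readGrammar(grammarFile, tree = trees[[1L]],
                   ncol = alignmentNcol(blocks[[1L]]))
  diag <- validateGrammar(g)
  if (any(diag$severity == "error"))
    stop("grammar failed validation:\n",
         paste(diag$message[diag$severity == "error"], collapse = "\n"),
         call. = FALSE)
  if (train) {
    fit <- emTrain(g, blocks, trees, maxIter = maxIter, tol = tol,
                   band = band)
    g <- fit$grammar
    if (!is.null(trainOut)) writeGrammar(g, trainOut)
  }
  annotations <- list()
  outLines <- character(0)
  allGff <- NULL
  wigTracks <- list()
  for (q in seq_along(blocks)) {
    b <- blocks[[q]]
    tr <- trees[[q]]
    b@gf[["NH"]] <- writeNewick(tr)
    if (annotate) {
      pa <- annotateAlignment(g, b, tr, band = band, ancestral = ancestral)
      annotations[[q]] <- pa
      for (rw in names(pa@gc)) b@gc[rw] <- pa@gc[rw]
      for (sq in names(pa@gr))
        b@gr[[sq]] <- c(b@gr[[sq]], pa@gr[[sq]])
      if (ancestral && length(pa@ancestral))
        b@seqs <- c(b@seqs, pa@ancestral)
      gf <- pa@gff
      if (length(blocks) > 1L && nrow(gf)) gf$seqid <- paste0("block", q)
      allGff <- if (is.null(allGff)) gf else rbind(allGff, gf)
      for (nt in names(pa@wig))
        wigTracks[[paste0(if (length(blocks) > 1L) paste0("block", q, ":"),
                          nt)]] <- pa@wig[[nt]]
    }
    outLines <- c(outLines, writeStockholm(b))
  }
  writeLines(outLines, out)
  if (annotate) {
    if (!is.null(gffFile)) writeGff(allGff, gffFile)
    if (!is.null(wigFile)) {
      con <- file(wigFile, "w")
      on.exit(close(con), add = TRUE)
      for (nm in names(wigTracks))
        writeWig(wigTracks[[nm]], con, name = nm)
    }
  }
  invisible(list(annotations = annotations, grammar = g, trees = trees))
}
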