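## Stockholm alignment format: sequences plus #=GF (file), #=GC (column)
## and #=GR (per-sequence, per-column) annotations, with an embedded Newick
## tree under the GF NH tag, blocks terminated by "//".

#' Stockholm multiple sequence alignment
#'
#' Ordered named rows over alphabet + gap + wildcard characters, with
#' file-level tags (\code{#=GF}), per-column annotation strings
#' (\code{#=GC}), per-sequence per-column annotation strings (\code{#=GR})
#' and an optional embedded Newick tree (the GF \code{NH} tag, possibly
#' split across lines).
#'
#' @slot seqs named character vector of aligned rows (equal lengths).
#' @slot gf named list of file-level tag values (character vectors; NH
#'   lines are kept here too, concatenated when the tree is parsed).
#' @slot gc named character vector of per-column annotation strings.
#' @slot gr named list (by sequence) of named character vectors (by tag).
#' @export
setClass("StockholmAlignment",
  representation(seqs = "character", gf = "list", gc = "character",
                 gr = "list"),
  prototype(seqs = setNames(character(0), character(0)), gf = list(),
            gc = setNames(character(0), character(0)), gr = list()))

setValidity("StockholmAlignment", function(object) {
  msgs <- character(0)
  L <- unique(nchar(object@seqs))
  if (length(L) > 1L) msgs <- c(msgs, "rows have unequal lengths")
  if (length(object@seqs) && is.null(names(object@seqs)))
    msgs <- c(msgs, "rows must be named")
  if (length(L) == 1L) {
    if (any(nchar(object@gc) != L))
      msgs <- c(msgs, "#=GC annotation length differs from row length")
    for (sq in names(object@gr))
      if (any(nchar(object@gr[[sq]]) != L))
        msgs <- c(msgs, paste0("#=GR annotation length mismatch for ", sq))
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn StockholmAlignment constructor.
#' @param seqs,gf,gc,gr see slots.
#' @param tree optional \code{\link{PhyloTree}} stored as the GF NH tag.
#' @export
stockholmAlignment <- function(seqs, gf = list(), gc = character(0),
                               gr = list(), tree = NULL) {
  if (length(gc) && is.null(names(gc))) stop("gc must be named")
  if (!is.null(tree)) gf[["NH"]] <- writeNewick(tree)
  new("StockholmAlignment", seqs = seqs, gf = gf,
      gc = if (length(gc)) gc else setNames(character(0), character(0)),
      gr = gr)
}

#' @describeIn StockholmAlignment the aligned rows (named character
#'   vector).
#' @param x a \code{StockholmAlignment}.
#' @export
alignmentRows <- function(x) x@seqs

#' @describeIn StockholmAlignment number of alignment columns.
#' @export
alignmentNcol <- function(x) {
  if (!length(x@seqs)) 0L else nchar(x@seqs[[1L]])
}

#' @describeIn StockholmAlignment the embedded tree (parsed from the GF NH
#'   tag), or \code{NULL}.
#' @export
alignmentTree <- function(x) {
  nh <- x@gf[["NH"]]
  if (is.null(nh)) return(NULL)
  parseNewick(paste(nh, collapse = ""))
}

setMethod("show", "StockholmAlignment", function(object) {
  cat("StockholmAlignment: ", length(object@seqs), " sequences x ",
      alignmentNcol(object), " columns",
      if (!is.null(object@gf[["NH"]])) "; embedded tree" else "",
      if (length(object@gc))
        paste0("; GC rows: ", paste(names(object@gc), collapse = ", "))
      else "", "\n", sep = "")
})

#' Read Stockholm alignments
#'
#' Parses one or more Stockholm blocks (multi-block files support batch
#' processing of many alignments).  Sequence and annotation lines split
#' across multiple occurrences are concatenated; NH lines are joined into
#' one Newick string.
#'
#' @param input file path or character vector of lines.
#' @return list of \code{\link{StockholmAlignment}} objects.
#' @export
readStockholm <- function(input) {
  lines <- if (length(input) == 1L && file.exists(input))
    readLines(input, warn = FALSE) else input
  blocks <- list()
  newBlock <- function() list(seqs = character(0), gf = list(),
                              gc = character(0), gr = list())
  cur <- newBlock()
  flush <- function() {
    if (length(cur$seqs) || length(cur$gf)) {
      blocks[[length(blocks) + 1L]] <<- new(
        "StockholmAlignment", seqs = cur$seqs, gf = cur$gf,
        gc = if (length(cur$gc)) cur$gc else
          setNames(character(0), character(0)),
        gr = cur$gr)
    }
    cur <<- newBlock()
  }
  for (raw in lines) {
    line <- sub("[\r\n]+$", "", raw)
    if (!nzchar(trimws(line))) next
    if (grepl("^# STOCKHOLM", line)) next
    if (line == "//") { flush(); next }
    if (startsWith(line, "#=GF")) {
      m <- regmatches(line, regexec("^#=GF\\s+(\\S+)\\s*(.*)$", line))[[1L]]
      cur$gf[[m[2L]]] <- c(cur$gf[[m[2L]]], m[3L])
    } else if (startsWith(line, "#=GC")) {
      m <- regmatches(line, regexec("^#=GC\\s+(\\S+)\\s+(\\S+)$", line))[[1L]]
      prev <- if (m[2L] %in% names(cur$gc)) cur$gc[[m[2L]]] else ""
      cur$gc[m[2L]] <- paste0(prev, m[3L])
    } else if (startsWith(line, "#=GR")) {
      m <- regmatches(line,
                      regexec("^#=GR\\s+(\\S+)\\s+(\\S+)\\s+(\\S+)$",
                              line))[[1L]]
      sq <- m[2L]; tag <- m[3L]
      if (is.null(cur$gr[[sq]])) cur$gr[[sq]] <- character(0)
      prev <- if (tag %in% names(cur$gr[[sq]])) cur$gr[[sq]][[tag]] else ""
      cur$gr[[sq]][tag] <- paste0(prev, m[4L])
    } else if (startsWith(line, "#")) {
      next
    } else {
      m <- regmatches(line, regexec("^(\\S+)\\s+(\\S+)$", line))[[1L]]
      if (length(m) != 3L)
        stop("malformed Stockholm sequence line: ", line, call. = FALSE)
      prev <- if (m[2L] %in% names(cur$seqs)) cur$seqs[[m[2L]]] else ""
      cur$seqs[m[2L]] <- paste0(prev, m[3L])
    }
  }
  flush()
  for (b in blocks) validObject(b)
  blocks
}

#' Write a Stockholm alignment
#'
#' Canonical form: header, \code{#=GF} tags (NH as one line), sequences
#' each followed by their \code{#=GR} rows, \code{#=GC} rows, then
#' \code{//}.  Reading the output back reproduces the object (round trip up
#' to line-wrapping normalization: the canonical form never wraps).
#'
#' @param aln a \code{\link{StockholmAlignment}} (or list of them).
#' @param file optional path; when omitted the lines are returned.
#' @return character vector of lines, invisibly when writing to a file.
#' @export
writeStockholm <- function(aln, file = NULL) {
  alns <- if (is(aln, "StockholmAlignment")) list(aln) else aln
  out <- character(0)
  for (a in alns) {
    out <- c(out, "# STOCKHOLM 1.0")
    for (tag in names(a@gf)) {
      val <- a@gf[[tag]]
      if (tag == "NH") val <- paste(val, collapse = "")
      for (v in val) out <- c(out, paste("#=GF", tag, v))
    }
    grKeys <- unlist(lapply(names(a@gr), function(sq)
      paste("#=GR", sq, names(a@gr[[sq]]))))
    nameW <- max(0L, nchar(names(a@seqs)), nchar(grKeys),
                 if (length(a@gc)) nchar(paste("#=GC", names(a@gc))))
    padTo <- function(s) formatC(s, width = nameW, flag = "-")
    for (sq in names(a@seqs)) {
      out <- c(out, paste(padTo(sq), a@seqs[[sq]]))
      if (!is.null(a@gr[[sq]]))
        for (tag in names(a@gr[[sq]]))
          out <- c(out, paste(padTo(paste("#=GR", sq, tag)),
                              a@gr[[sq]][[tag]]))
    }
    for (tag in names(a@gc))
      out <- c(out, paste(padTo(paste("#=GC", tag)), a@gc[[tag]]))
    out <- c(out, "//")
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
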