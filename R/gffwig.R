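## GFF (discrete features) and WIG (per-column quantitative values) output.

#' Build GFF features from per-column labels
#'
#' One feature per maximal run of identically labeled columns, in 1-based
#' inclusive alignment-column coordinates.  The score is the mean per-column
#' posterior over the run when a posterior matrix is given.
#'
#' @param labels per-column label vector (\code{NA} columns are skipped).
#' @param seqid the GFF seqid (the alignment name).
#' @param source the GFF source field.
#' @param posterior optional columns x labels posterior matrix for scores.
#' @return data.frame with the 9 GFF columns.
#' @export
gffFeatures <- function(labels, seqid = "alignment", source = "phygram",
                        posterior = NULL) {
  out <- data.frame(seqid = character(0), source = character(0),
                    type = character(0), start = integer(0), end = integer(0),
                    score = character(0), strand = character(0),
                    frame = character(0), attributes = character(0),
                    stringsAsFactors = FALSE)
  L <- length(labels)
  i <- 1L
  while (i <= L) {
    if (is.na(labels[i])) { i <- i + 1L; next }
    j <- i
    while (j < L && !is.na(labels[j + 1L]) && labels[j + 1L] == labels[i])
      j <- j + 1L
    score <- "."
    if (!is.null(posterior) && labels[i] %in% colnames(posterior))
      score <- formatC(mean(posterior[i:j, labels[i]]), digits = 4,
                       format = "f")
    out <- rbind(out, data.frame(
      seqid = seqid, source = source, type = labels[i], start = i, end = j,
      score = score, strand = ".", frame = ".",
      attributes = paste0("Nonterminal \"", labels[i], "\""),
      stringsAsFactors = FALSE))
    i <- j + 1L
  }
  out
}

#' Write GFF features
#'
#' Emits one line per feature with exactly 9 tab-delimited fields
#' (GFF version 2 attribute syntax), to standard output by default.
#'
#' @param features data.frame as from \code{\link{gffFeatures}}.
#' @param file connection or path; \code{""} = standard output.
#' @return invisibly, the lines written.
#' @export
writeGff <- function(features, file = "") {
  header <- "##gff-version 2"
  lines <- header
  if (!is.null(features) && nrow(features)) {
    lines <- c(lines, apply(features, 1L, function(row)
      paste(row[c("seqid", "source", "type", "start", "end", "score",
                  "strand", "frame", "attributes")], collapse = "\t")))
  }
  writeLines(lines, file)
  invisible(lines)
}

#' Write a WIG track
#'
#' fixedStep track with step 1 over alignment columns (1-based); one value
#' per column.
#'
#' @param values numeric vector of per-column values (probabilities when
#'   derived from posteriors).
#' @param file connection or path; \code{""} = standard output.
#' @param chrom the chrom field of the fixedStep header.
#' @param name track name.
#' @param start 1-based start coordinate.
#' @return invisibly, the lines written.
#' @export
writeWig <- function(values, file = "", chrom = "alignment",
                     name = "posterior", start = 1L) {
  lines <- c(sprintf("track type=wiggle_0 name=\"%s\"", name),
             sprintf("fixedStep chrom=%s start=%d step=1", chrom, start),
             formatC(values, digits = 6, format = "g"))
  writeLines(lines, file)
  invisible(lines)
}
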