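## S-expression reading and writing.
##
## Grammar files are Lisp-style S-expressions: atoms separated by whitespace,
## lists delimited by parentheses, ";;" comments running to end of line.
## Parsed expressions are represented as plain R objects: an atom is a
## length-1 character vector, a list is an R list of expressions.  This makes
## structural identity a plain identical() and keeps expansion code simple.
## Source positions are tracked only while tokenizing, for error messages.

#' Test whether an S-expression is an atom
#'
#' Atoms are length-1 character vectors; lists are R lists.
#'
#' @param x object to test.
#' @return \code{TRUE} for an atom.
#' @export
isAtom <- function(x) is.character(x) && length(x) == 1L

#' @rdname isAtom
#' @export
isSList <- function(x) is.list(x)

## Tokenize text into atoms and parens, keeping line/column for errors.
## Comments start at ";" and run to end of line (";;" in grammar files).
sexprTokenize <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  toks <- character(0)
  tlin <- integer(0)
  tcol <- integer(0)
  for (ln in seq_along(lines)) {
    s <- lines[ln]
    s <- sub(";.*$", "", s)
    n <- nchar(s)
    i <- 1L
    while (i <= n) {
      ch <- substr(s, i, i)
      if (grepl("^[[:space:]]$", ch)) {
        i <- i + 1L
      } else if (ch == "(" || ch == ")") {
        toks <- c(toks, ch); tlin <- c(tlin, ln); tcol <- c(tcol, i)
        i <- i + 1L
      } else {
        j <- i
        while (j <= n) {
          cj <- substr(s, j, j)
          if (cj == "(" || cj == ")" || grepl("^[[:space:]]$", cj)) break
          j <- j + 1L
        }
        toks <- c(toks, substr(s, i, j - 1L)); tlin <- c(tlin, ln); tcol <- c(tcol, i)
        i <- j
      }
    }
  }
  list(tokens = toks, line = tlin, col = tcol)
}

#' Parse S-expression text
#'
#' Parses one or more top-level S-expressions.  The result is always a list
#' whose elements are the top-level expressions (a "forest"); empty input
#' yields an empty list.  Atom spelling is preserved exactly; comments
#' (\code{;;} to end of line) are discarded.
#'
#' @param text character vector of S-expression source (lines or one string).
#' @return list of parsed expressions (atoms are character scalars, lists are
#'   R lists).
#' @examples
#' parseSExpr("(a (b c))")[[1]]
#' @export
parseSExpr <- function(text) {
  tk <- sexprTokenize(text)
  toks <- tk$tokens
  pos <- 1L
  npos <- length(toks)
  perr <- function(msg, at) {
    if (at <= npos)
      stop(sprintf("S-expression parse error at line %d, column %d: %s",
                   tk$line[at], tk$col[at], msg), call. = FALSE)
    stop(sprintf("S-expression parse error at end of input: %s", msg),
         call. = FALSE)
  }
  parseOne <- function() {
    if (pos > npos) perr("unexpected end of input", pos)
    t <- toks[pos]
    if (t == "(") {
      open <- pos
      pos <<- pos + 1L
      out <- list()
      repeat {
        if (pos > npos) perr("unbalanced parenthesis (missing ')')", open)
        if (toks[pos] == ")") {
          pos <<- pos + 1L
          return(out)
        }
        out[[length(out) + 1L]] <- parseOne()
      }
    } else if (t == ")") {
      perr("unbalanced parenthesis (unexpected ')')", pos)
    } else {
      pos <<- pos + 1L
      t
    }
  }
  forest <- list()
  while (pos <= npos) forest[[length(forest) + 1L]] <- parseOne()
  forest
}

#' Serialize an S-expression
#'
#' Deterministic writer: atoms verbatim, lists space-separated inside
#' parentheses.  \code{writeSExprForest} writes top-level expressions one per
#' line.  Re-parsing the output yields a structurally identical expression.
#'
#' @param x an S-expression (atom or list).
#' @return a character scalar.
#' @export
writeSExpr <- function(x) {
  if (isAtom(x)) return(x)
  if (!is.list(x)) stop("not an S-expression")
  paste0("(", paste(vapply(x, writeSExpr, character(1)), collapse = " "), ")")
}

#' @rdname writeSExpr
#' @param forest list of top-level expressions.
#' @export
writeSExprForest <- function(forest) {
  paste(vapply(forest, writeSExpr, character(1)), collapse = "\n")
}

## Pretty-printer used when emitting whole grammars: one top-level block per
## line, with chain/grammar blocks broken across lines for readability.
formatSExprBlock <- function(x, indent = 0L, width = 100L) {
  flat <- writeSExpr(x)
  pad <- strrep(" ", indent)
  if (isAtom(x) || nchar(flat) + indent <= width) return(paste0(pad, flat))
  head <- if (length(x) > 0L && isAtom(x[[1L]])) x[[1L]] else NULL
  if (is.null(head)) {
    inner <- vapply(x, formatSExprBlock, character(1),
                    indent = indent + 1L, width = width)
    return(paste0(pad, "(\n", paste(inner, collapse = "\n"), ")"))
  }
  inner <- vapply(x[-1L], formatSExprBlock, character(1),
                  indent = indent + 1L, width = width)
  paste0(pad, "(", head, "\n", paste(inner, collapse = "\n"), ")")
}
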