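## Alphabets over which substitution chains run.

#' @import methods
NULL

#' Alphabet of substitution tokens
#'
#' An ordered set of tokens (e.g. the DNA bases, or the sense codons of a
#' genetic code), with an optional complement map, wildcard characters
#' (matching any token) and gap characters (treated as missing data).
#' Token order is the order of declaration and fixes state indexing
#' everywhere downstream.
#'
#' @slot name alphabet name.
#' @slot tokens ordered character vector of unique tokens.
#' @slot complement named character vector (an involution on tokens), or
#'   empty.
#' @slot wildcards characters standing for "any token".
#' @slot gapChars characters treated as alignment gaps (missing data).
#' @export
setClass("Alphabet",
  representation(name = "character", tokens = "character",
                 complement = "character", wildcards = "character",
                 gapChars = "character"),
  prototype(name = "alphabet", complement = character(0),
            wildcards = c("*", "n", "x"), gapChars = c("-", ".")))

setValidity("Alphabet", function(object) {
  msgs <- character(0)
  if (length(object@tokens) == 0L) msgs <- c(msgs, "alphabet has no tokens")
  if (anyDuplicated(object@tokens)) msgs <- c(msgs, "tokens are not unique")
  if (any(!nzchar(object@tokens))) msgs <- c(msgs, "empty token")
  if (length(object@complement) > 0L) {
    if (!setequal(names(object@complement), object@tokens) ||
        !all(object@complement %in% object@tokens))
      msgs <- c(msgs, "complement map must be defined on the tokens")
    else {
      inv <- object@complement[object@complement]
      if (!identical(unname(inv), names(object@complement)))
        msgs <- c(msgs, "complement map is not an involution")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn Alphabet constructor.
#' @param name,tokens,complement,wildcards,gapChars see slots.
#' @export
alphabet <- function(name, tokens, complement = character(0),
                     wildcards = c("*", "n", "x"), gapChars = c("-", ".")) {
  new("Alphabet", name = name, tokens = as.character(tokens),
      complement = complement, wildcards = wildcards, gapChars = gapChars)
}

#' @describeIn Alphabet the 4-token DNA alphabet (a, c, g, t) with
#'   Watson-Crick complement.
#' @export
dnaAlphabet <- function() {
  alphabet("DNA", c("a", "c", "g", "t"),
           complement = c(a = "t", c = "g", g = "c", t = "a"))
}

#' @describeIn Alphabet ordered tokens.
#' @param x an \code{Alphabet}.
#' @export
alphabetTokens <- function(x) x@tokens

setMethod("show", "Alphabet", function(object) {
  cat("Alphabet '", object@name, "': ", length(object@tokens), " tokens (",
      paste(utils::head(object@tokens, 8L), collapse = " "),
      if (length(object@tokens) > 8L) " ..." else "", ")\n", sep = "")
})

#' Sense codons of a genetic code
#'
#' Enumerates the non-stop codons of a genetic code table in nested
#' a/c/g/t order (first position slowest).  Codons are lowercase 3-letter
#' strings.
#'
#' @param code a genetic code: a named character vector mapping the 64
#'   codons (uppercase, T not U) to amino-acid letters with \code{"*"} for
#'   stop, as returned by \code{Biostrings::getGeneticCode}.
#' @return character vector of sense codons (61 for the standard code).
#' @export
senseCodons <- function(code = Biostrings::getGeneticCode("1")) {
  checkGeneticCode(code)
  nt <- c("a", "c", "g", "t")
  all <- sort(as.vector(outer(outer(nt, nt, paste0), nt, paste0)))
  # a-c-g-t nested order, first position slowest
  aa <- code[toupper(all)]
  all[aa != "*"]
}

checkGeneticCode <- function(code) {
  nt <- c("A", "C", "G", "T")
  need <- as.vector(outer(outer(nt, nt, paste0), nt, paste0))
  if (!all(need %in% names(code)))
    stop("genetic code table must cover all 64 codons", call. = FALSE)
  invisible(code)
}

#' @describeIn Alphabet an alphabet whose tokens are the sense codons of a
#'   genetic code.
#' @param code genetic code table (see \code{\link{senseCodons}}).
#' @export
codonAlphabet <- function(code = Biostrings::getGeneticCode("1")) {
  alphabet(name = "Codon", tokens = senseCodons(code),
           wildcards = "*", gapChars = c("-", "."))
}

## Indices of tokens compatible with an observed character: wildcards, gaps
## and unknown characters all act as missing data (every token possible).
tokenIndicator <- function(alph, obs) {
  idx <- match(obs, alph@tokens)
  if (!is.na(idx)) {
    v <- numeric(length(alph@tokens)); v[idx] <- 1; return(v)
  }
  rep(1, length(alph@tokens))
}
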