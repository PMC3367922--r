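## The Grammar data model: nonterminals, production rules, chains and
## parameters; reading and writing the macro-free S-expression dialect;
## validation diagnostics; phylo-HMM vs phylo-SCFG classification.

#' Phylogenetic grammar
#'
#' The central model object: an alphabet, a set of substitution chains
#' (possibly lineage-specific hybrid chains), nonterminals with a designated
#' start symbol, production rules, a parameter set and per-nonterminal
#' annotation directives used when writing \code{#=GC}/GFF/WIG output.
#'
#' Rules are stored as lists with a \code{kind} field:
#' \describe{
#'   \item{transition}{\code{lhs -> to} with probability expression.}
#'   \item{emission}{\code{lhs -> (left terminals, nxt, right terminals)};
#'     always probability 1; \code{chain} names the emitting chain.}
#'   \item{return}{a transition whose lhs is an emission's starred
#'     continuation nonterminal.}
#'   \item{bifurcation}{\code{lhs -> (to[1], to[2])}.}
#'   \item{end}{\code{lhs -> ()} with an (unnormalized) weight.}
#' }
#'
#' @slot name grammar name.
#' @slot alphabet an \code{\link{Alphabet}}.
#' @slot chains named list of \code{\link{Chain}}/\code{\link{HybridChain}},
#'   keyed by first pseudoterminal name.
#' @slot nonterms all nonterminal names.
#' @slot start the start nonterminal.
#' @slot rules list of rule records.
#' @slot params a \code{\link{ParamSet}}.
#' @slot annotations data.frame with columns nonterm, row, label.
#' @export
setClass("Grammar",
  representation(name = "character", alphabet = "Alphabet",
                 chains = "list", nonterms = "character", start = "character",
                 rules = "list", params = "ParamSet",
                 annotations = "data.frame"))

emptyAnnotations <- function() {
  data.frame(nonterm = character(0), row = character(0),
             label = character(0), stringsAsFactors = FALSE)
}

#' @describeIn Grammar constructor (rule kinds are derived from the rule
#'   shapes; see \code{\link{readGrammar}} for the file dialect).
#' @param name,alphabet,chains,rules,params,start,annotations see slots.
#' @export
makeGrammar <- function(name, alphabet, chains, rules, params,
                        start = "start", annotations = emptyAnnotations()) {
  names(chains) <- vapply(chains, function(ch)
    if (is(ch, "HybridChain")) ch@terminals[1L] else ch@terminals[1L],
    character(1))
  rules <- classifyRules(rules, chains)
  nonterms <- unique(c(start, unlist(lapply(rules, function(r)
    c(r$lhs, r$nxt, if (r$kind %in% c("transition", "return", "bifurcation"))
        r$to else NULL)))))
  new("Grammar", name = name, alphabet = alphabet, chains = chains,
      nonterms = nonterms, start = start, rules = rules, params = params,
      annotations = annotations)
}

## All pseudoterminal names of a chain (hybrid or plain).
chainTerminals <- function(ch) {
  if (is(ch, "HybridChain")) ch@terminals else ch@terminals
}

## Derive rule kinds from raw records {lhs, rhs (character vector), prob}.
classifyRules <- function(rules, chains) {
  termMap <- character(0)     # pseudoterminal name -> chain key
  for (key in names(chains)) {
    tt <- chainTerminals(chains[[key]])
    termMap[tt] <- key
  }
  out <- vector("list", length(rules))
  emitStars <- character(0)
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    if (!is.null(r$kind) && r$kind == "emission") {
      emitStars <- c(emitStars, r$nxt)
      out[[i]] <- r
      next
    }
    rhs <- r$rhs
    isTerm <- rhs %in% names(termMap)
    if (length(rhs) == 0L) {
      out[[i]] <- list(kind = "end", lhs = r$lhs,
                       prob = if (is.null(r$prob)) "1" else r$prob)
    } else if (any(isTerm)) {
      nts <- which(!isTerm)
      if (length(nts) != 1L)
        stop("emission rule must contain exactly one nonterminal: ",
             r$lhs, " -> (", paste(rhs, collapse = " "), ")", call. = FALSE)
      terms <- rhs[isTerm]
      keys <- unique(termMap[terms])
      if (length(keys) != 1L)
        stop("emission mixes pseudoterminals of different chains: ",
             paste(terms, collapse = " "), call. = FALSE)
      ch <- chains[[keys]]
      want <- chainTerminals(ch)
      left <- rhs[seq_len(nts - 1L)]
      right <- if (nts < length(rhs)) rhs[(nts + 1L):length(rhs)] else
        character(0)
      if (!identical(c(left, right), want))
        stop("emission pseudoterminals must be exactly the chain's, in ",
             "order: expected (", paste(want, collapse = " "), "), got (",
             paste(terms, collapse = " "), ")", call. = FALSE)
      emitStars <- c(emitStars, rhs[nts])
      out[[i]] <- list(kind = "emission", lhs = r$lhs, chain = keys,
                       left = length(left), right = length(right),
                       nxt = rhs[nts], prob = "1")
    } else if (length(rhs) == 1L) {
      out[[i]] <- list(kind = "transition", lhs = r$lhs, to = rhs,
                       prob = if (is.null(r$prob)) "1" else r$prob)
    } else if (length(rhs) == 2L) {
      out[[i]] <- list(kind = "bifurcation", lhs = r$lhs, to = rhs,
                       prob = if (is.null(r$prob)) "1" else r$prob)
    } else {
      stop("rule right-hand side with more than two nonterminals: ",
           r$lhs, " -> (", paste(rhs, collapse = " "), ")", call. = FALSE)
    }
  }
  for (i in seq_along(out)) {
    if (out[[i]]$kind == "transition" && out[[i]]$lhs %in% emitStars)
      out[[i]]$kind <- "return"
  }
  out
}

setMethod("show", "Grammar", function(object) {
  kinds <- vapply(object@rules, function(r) r$kind, character(1))
  cat("Grammar '", object@name, "' (", classifyGrammar(object), ")\n",
      "  alphabet: ", object@alphabet@name, " (",
      length(object@alphabet@tokens), " tokens)\n",
      "  nonterminals: ", length(object@nonterms),
      " (start: ", object@start, ")\n",
      "  chains: ", length(object@chains), "; rules: ",
      length(object@rules), " (",
      paste(names(table(kinds)), table(kinds), sep = "=", collapse = ", "),
      ")\n",
      "  free parameters: ", length(freeParams(object@params)), "\n",
      sep = "")
})

#' @describeIn Grammar the production rules.
#' @param g a \code{Grammar}.
#' @export
grammarRules <- function(g) g@rules

#' @describeIn Grammar the parameter set.
#' @export
grammarParams <- function(g) g@params

#' @describeIn Grammar replace the parameter set.
#' @param value a \code{ParamSet}.
#' @export
`grammarParams<-` <- function(g, value) { g@params <- value; g }

#' @describeIn Grammar the chains, keyed by first pseudoterminal.
#' @export
grammarChains <- function(g) g@chains

#' @describeIn Grammar nonterminals that have an emission rule.
#' @export
emittingNonterms <- function(g) {
  unique(vapply(Filter(function(r) r$kind == "emission", g@rules),
                function(r) r$lhs, character(1)))
}

## ---- reading the S-expression dialect --------------------------------------

sexprPairs <- function(blocks) {
  ## (name value) pairs -> named numeric
  out <- numeric(0)
  for (b in blocks) {
    if (!isSList(b) || length(b) != 2L || !isAtom(b[[1L]]))
      stop("expected (name value) pair, got: ", writeSExpr(b), call. = FALSE)
    v <- atomNumber(b[[2L]])
    if (is.na(v)) stop("non-numeric parameter value: ", writeSExpr(b),
                       call. = FALSE)
    out[b[[1L]]] <- v
  }
  out
}

## (rate (n v) (n v)...) or the unwrapped single-pair form (rate n v).
sexprParamBlock <- function(e) {
  body <- e[-1L]
  if (length(body) == 2L && isAtom(body[[1L]]) && isAtom(body[[2L]]))
    return(sexprPairs(list(body)))
  sexprPairs(body)
}

blockChildren <- function(block, tag) {
  Filter(function(e) isSList(e) && length(e) >= 1L && isAtom(e[[1L]]) &&
           e[[1L]] == tag, block[-1L])
}

childValue <- function(block, tag, default = NULL) {
  hits <- blockChildren(block, tag)
  if (length(hits) == 0L) return(default)
  hits[[1L]][-1L]
}

atomsOf <- function(x) {
  if (isAtom(x)) return(x)
  vapply(x, function(e) {
    if (!isAtom(e)) stop("expected atom, got: ", writeSExpr(e), call. = FALSE)
    e
  }, character(1))
}

## A (prob f1 f2 ...) or (rate f1 f2 ...) body: atoms and/or one nested list
## of factors (the product form emitted by symbolic macro division).
exprFactors <- function(parts) {
  out <- character(0)
  for (p in parts) {
    if (isAtom(p)) out <- c(out, p)
    else out <- c(out, vapply(p, function(e) {
      if (!isAtom(e)) stop("bad factor in expression: ", writeSExpr(e),
                           call. = FALSE)
      e
    }, character(1)))
  }
  if (length(out) == 0L) "1" else out
}

parseAlphabetBlock <- function(block) {
  nm <- childValue(block, "name", list("alphabet"))[[1L]]
  toks <- atomsOf(childValue(block, "token", stop("alphabet needs (token ...)",
                                                  call. = FALSE))[[1L]])
  comp <- character(0)
  cb <- childValue(block, "complement")
  if (!is.null(cb)) {
    cv <- atomsOf(cb[[1L]])
    comp <- setNames(cv, toks)
  }
  wc <- childValue(block, "wildcard")
  if (!is.null(wc) && length(wc) == 1L && isSList(wc[[1L]])) wc <- wc[[1L]]
  wild <- if (is.null(wc)) c("*", "n", "x") else atomsOf(wc)
  alphabet(nm, toks, complement = comp, wildcards = wild)
}

parseStateSpec <- function(x, arity) {
  ## (state (toks... [class])) inner list
  parts <- atomsOf(x)
  if (length(parts) == arity) list(tokens = parts, class = "")
  else if (length(parts) == arity + 1L)
    list(tokens = parts[seq_len(arity)], class = parts[arity + 1L])
  else stop("state tuple of wrong arity: (", paste(parts, collapse = " "),
            ")", call. = FALSE)
}

parseChainBlock <- function(block, alph) {
  termSpec <- childValue(block, "terminal",
                         stop("chain needs (terminal ...)", call. = FALSE))
  terminals <- atomsOf(termSpec[[1L]])
  arity <- length(terminals)
  classRow <- NA_character_
  classLabels <- character(0)
  hc <- blockChildren(block, "hidden-class")
  if (length(hc)) {
    classRow <- atomsOf(childValue(hc[[1L]], "row")[[1L]])
    classLabels <- atomsOf(childValue(hc[[1L]], "label")[[1L]])
  }
  initial <- list()
  mutate <- list()
  for (e in blockChildren(block, "initial")) {
    st <- parseStateSpec(childValue(e, "state")[[1L]], arity)
    nm <- chainStateName(st$tokens, st$class)
    initial[[nm]] <- exprFactors(childValue(e, "prob", list("1")))
  }
  for (e in blockChildren(block, "mutate")) {
    fr <- parseStateSpec(childValue(e, "from")[[1L]], arity)
    to <- parseStateSpec(childValue(e, "to")[[1L]], arity)
    mutate[[length(mutate) + 1L]] <- list(
      from = chainStateName(fr$tokens, fr$class),
      to = chainStateName(to$tokens, to$class),
      expr = exprFactors(childValue(e, "rate", list("1"))))
  }
  makeChain(alph, terminals, classRow = classRow, classLabels = classLabels,
            initial = initial, mutate = mutate)
}

parseHybridBlock <- function(block, chains) {
  terminals <- atomsOf(childValue(block, "terminal")[[1L]])
  selector <- childValue(block, "selector", list("node-label"))[[1L]]
  lookup <- function(tname) {
    for (ch in chains)
      if (!is(ch, "HybridChain") && tname %in% ch@terminals) return(ch)
    stop("hybrid-chain component references unknown chain terminal: ",
         tname, call. = FALSE)
  }
  comps <- list()
  for (e in blockChildren(block, "component")) {
    lab <- atomsOf(childValue(e, "label")[[1L]])
    tn <- atomsOf(childValue(e, "terminal")[[1L]])[1L]
    for (l in lab) comps[[l]] <- lookup(tn)
  }
  defSpec <- childValue(block, "default",
                        stop("hybrid-chain needs (default (terminal ...))",
                             call. = FALSE))
  defTerm <- atomsOf(defSpec[[1L]][-1L])[1L]
  hybridChain(terminals, comps, lookup(defTerm), selector = selector)
}

#' Read a grammar file
#'
#' Parses S-expression text, expands macros (using the declared alphabet,
#' and a tree/alignment where supplied, as expansion context — the alphabet
#' is parsed first since macros may depend on it), and assembles the
#' \code{\link{Grammar}}.  Accepts a file path, character text, or an
#' already-parsed forest.
#'
#' @param x file path, S-expression text, or parsed forest.
#' @param tree optional \code{\link{PhyloTree}} for tree-iterator macros.
#' @param ncol optional alignment column count for column iterators.
#' @param alphabet fallback \code{\link{Alphabet}} when the file declares
#'   none.
#' @param includeDirs extra directories for \code{&include}.
#' @return a \code{\link{Grammar}}.
#' @export
readGrammar <- function(x, tree = NULL, ncol = NULL, alphabet = NULL,
                        includeDirs = character(0)) {
  srcFile <- NULL
  if (is.character(x)) {
    if (length(x) == 1L && !grepl("(", x, fixed = TRUE) && file.exists(x)) {
      srcFile <- x
      x <- readLines(x, warn = FALSE)
    }
    forest <- parseSExpr(x)
  } else forest <- x
  ## Pass 1: the alphabet (macros may depend on it).
  isBlock <- function(e, tag) isSList(e) && length(e) && isAtom(e[[1L]]) &&
    e[[1L]] == tag
  alphIdx <- which(vapply(forest, isBlock, logical(1), tag = "alphabet"))
  if (length(alphIdx)) {
    env0 <- macroEnv()
    if (!is.null(srcFile)) env0$file <- srcFile
    ablock <- expandMacros(forest[[alphIdx[1L]]], env0)
    alph <- parseAlphabetBlock(ablock)
  } else if (!is.null(alphabet)) {
    alph <- alphabet
  } else stop("grammar file declares no alphabet and none was supplied",
              call. = FALSE)
  ## Pass 2: expand everything with full context.
  env <- macroEnv(tokens = alph@tokens, tree = tree, ncol = ncol,
                  includeDirs = includeDirs)
  if (!is.null(srcFile)) env$file <- srcFile
  expanded <- expandForest(forest, env)
  gIdx <- which(vapply(expanded, isBlock, logical(1), tag = "grammar"))
  if (!length(gIdx)) stop("no (grammar ...) block found", call. = FALSE)
  assembleGrammar(expanded[[gIdx[1L]]], alph)
}

assembleGrammar <- function(gblock, alph) {
  name <- childValue(gblock, "name", list("grammar"))[[1L]]
  rates <- numeric(0); consts <- numeric(0); pgroups <- list()
  chains <- list(); rawRules <- list()
  ann <- emptyAnnotations()
  hybridBlocks <- list()
  for (e in gblock[-1L]) {
    if (!isSList(e) || !length(e) || !isAtom(e[[1L]])) next
    tag <- e[[1L]]
    if (tag == "rate") {
      rates <- c(rates, sexprParamBlock(e))
    } else if (tag == "const") {
      consts <- c(consts, sexprParamBlock(e))
    } else if (tag == "pgroup") {
      pgroups[[length(pgroups) + 1L]] <- sexprPairs(e[-1L])
    } else if (tag == "chain") {
      ch <- parseChainBlock(e, alph)
      chains[[ch@terminals[1L]]] <- ch
    } else if (tag == "hybrid-chain") {
      hybridBlocks[[length(hybridBlocks) + 1L]] <- e
    } else if (tag == "transform") {
      fr <- atomsOf(childValue(e, "from")[[1L]])
      if (length(fr) != 1L)
        stop("transform (from ...) must name one symbol", call. = FALSE)
      toSpec <- childValue(e, "to", list(list()))[[1L]]
      to <- if (isSList(toSpec) && length(toSpec) == 0L) character(0)
            else atomsOf(toSpec)
      pr <- childValue(e, "prob")
      rawRules[[length(rawRules) + 1L]] <-
        list(lhs = fr, rhs = to,
             prob = if (is.null(pr)) NULL else exprFactors(pr))
    } else if (tag == "annotate") {
      ann <- rbind(ann, data.frame(
        nonterm = atomsOf(childValue(e, "nonterminal")[[1L]]),
        row = childValue(e, "row", list("STATE"))[[1L]],
        label = childValue(e, "label", list("."))[[1L]],
        stringsAsFactors = FALSE))
    } else if (tag %in% c("name", "update-rules", "update-rates",
                          "parametric")) {
      ## recognized but irrelevant here
    } else {
      warning("ignoring unrecognized grammar block: (", tag, " ...)",
              call. = FALSE)
    }
  }
  for (hb in hybridBlocks) {
    hc <- parseHybridBlock(hb, chains)
    chains[[hc@terminals[1L]]] <- hc
  }
  if (length(pgroups))
    names(pgroups) <- paste0("pgroup", seq_along(pgroups))
  params <- paramSet(rates = rates, pgroups = pgroups, consts = consts)
  start <- if (any(vapply(rawRules, function(r) r$lhs == "start",
                          logical(1)))) "start"
           else rawRules[[1L]]$lhs
  makeGrammar(name, alph, chains, rawRules, params, start = start,
              annotations = ann)
}

## ---- writing the dialect ---------------------------------------------------

fmtPair <- function(nm, v) list(nm, formatNum(v))

chainToSExpr <- function(ch) {
  out <- list("chain", list("terminal", as.list(ch@terminals)))
  if (length(ch@classLabels))
    out <- c(out, list(list("hidden-class", list("row", ch@classRow),
                            list("label", as.list(ch@classLabels)))))
  stateSpec <- function(nm) {
    i <- match(nm, ch@stateNames)
    toks <- as.list(ch@stateTokens[i, ])
    if (nzchar(ch@stateClass[i])) c(toks, list(ch@stateClass[i])) else toks
  }
  for (nm in names(ch@initial))
    out <- c(out, list(list("initial", list("state", stateSpec(nm)),
                            c(list("prob"), as.list(ch@initial[[nm]])))))
  for (m in ch@mutate)
    out <- c(out, list(list("mutate", list("from", stateSpec(m$from)),
                            list("to", stateSpec(m$to)),
                            c(list("rate"), as.list(m$expr)))))
  out
}

hybridToSExpr <- function(hc) {
  out <- list("hybrid-chain", list("terminal", as.list(hc@terminals)),
              list("selector", hc@selector))
  for (nm in names(hc@components))
    out <- c(out, list(list("component", list("label", nm),
                            list("terminal",
                                 hc@components[[nm]]@terminals[1L]))))
  c(out, list(list("default",
                   list("terminal", hc@default@terminals[1L]))))
}

ruleToSExpr <- function(r, chains) {
  rhs <- switch(r$kind,
    end = list(),
    transition = ,
    return = as.list(r$to),
    bifurcation = as.list(r$to),
    emission = {
      tt <- chainTerminals(chains[[r$chain]])
      c(as.list(tt[seq_len(r$left)]), list(r$nxt),
        if (r$right > 0L) as.list(tt[(r$left + 1L):(r$left + r$right)]))
    })
  out <- list("transform", list("from", list(r$lhs)), list("to", rhs))
  if (r$kind != "emission" && !identical(r$prob, "1"))
    out <- c(out, list(c(list("prob"), as.list(r$prob))))
  out
}

#' Write a grammar in the S-expression dialect
#'
#' Emits the macro-free dialect (alphabet, rate/pgroup/const, chain,
#' hybrid-chain, transform, annotate blocks).  Output is byte-stable for
#' identical inputs, so trained grammars can be diffed.
#'
#' @param g a \code{\link{Grammar}}.
#' @param file optional path; when omitted the text is returned.
#' @return the serialized text, invisibly when writing to a file.
#' @export
writeGrammar <- function(g, file = NULL) {
  p <- g@params
  gb <- list("grammar", list("name", g@name))
  if (length(p@rates))
    gb <- c(gb, list(c(list("rate"), mapply(fmtPair, names(p@rates),
                                            p@rates, SIMPLIFY = FALSE))))
  for (grp in p@pgroups)
    gb <- c(gb, list(c(list("pgroup"), mapply(fmtPair, names(grp), grp,
                                              SIMPLIFY = FALSE))))
  if (length(p@consts))
    gb <- c(gb, list(c(list("const"), mapply(fmtPair, names(p@consts),
                                             p@consts, SIMPLIFY = FALSE))))
  plainChains <- Filter(function(ch) !is(ch, "HybridChain"), g@chains)
  hybrids <- Filter(function(ch) is(ch, "HybridChain"), g@chains)
  ## component chains referenced only inside hybrids still need chain blocks
  aux <- list()
  for (hc in hybrids)
    for (cc in c(hc@components, list(hc@default))) {
      key <- cc@terminals[1L]
      if (!(key %in% names(plainChains)) && !(key %in% names(aux)))
        aux[[key]] <- cc
    }
  for (ch in c(plainChains, aux)) gb <- c(gb, list(chainToSExpr(ch)))
  for (hc in hybrids) gb <- c(gb, list(hybridToSExpr(hc)))
  for (r in g@rules) gb <- c(gb, list(ruleToSExpr(r, g@chains)))
  if (nrow(g@annotations))
    for (i in seq_len(nrow(g@annotations)))
      gb <- c(gb, list(list("annotate",
                            list("nonterminal", g@annotations$nonterm[i]),
                            list("row", g@annotations$row[i]),
                            list("label", g@annotations$label[i]))))
  ab <- list("alphabet", list("name", g@alphabet@name),
             list("token", as.list(g@alphabet@tokens)))
  if (length(g@alphabet@complement))
    ab <- c(ab, list(list("complement",
                          as.list(unname(g@alphabet@complement[
                            g@alphabet@tokens])))))
  ab <- c(ab, list(list("wildcard", as.list(g@alphabet@wildcards))))
  txt <- paste(c(formatSExprBlock(ab), formatSExprBlock(gb), ""),
               collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

## ---- validation ------------------------------------------------------------

diagRow <- function(severity, where, message) {
  data.frame(severity = severity, where = where, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a grammar
#'
#' Checks every structural invariant and returns one diagnostic per
#' violation (a data frame with severity, location and message); an empty
#' data frame means the grammar is clean.  Errors mark invariant violations;
#' warnings mark structurally legal but suspicious constructs, such as a
#' mutate entry that changes token and hidden class simultaneously.
#'
#' @param g a \code{\link{Grammar}}.
#' @return data.frame of diagnostics (zero rows if clean).
#' @export
validateGrammar <- function(g) {
  d <- emptyDiag <- diagRow(character(0), character(0), character(0))
  av <- validObject(g@alphabet, test = TRUE)
  if (is.character(av))
    for (m in av) d <- rbind(d, diagRow("error", "alphabet", m))
  p <- g@params
  if (any(p@rates < 0))
    d <- rbind(d, diagRow("error", "params", "negative rate parameter"))
  for (gn in names(p@pgroups)) {
    s <- sum(p@pgroups[[gn]])
    if (abs(s - 1) > 1e-9)
      d <- rbind(d, diagRow("error", gn,
                            sprintf("pgroup not normalizable (sum %g)", s)))
  }
  known <- c(names(p@rates), unlist(lapply(p@pgroups, names)),
             names(p@consts))
  checkExpr <- function(expr, where) {
    for (f in expr) {
      if (is.na(atomNumber(f)) && !(f %in% known))
        d <<- rbind(d, diagRow("error", where,
                               paste0("undeclared parameter: ", f)))
    }
  }
  eachPlain <- function(ch, key) {
    cv <- validObject(ch, test = TRUE)
    if (is.character(cv))
      for (m in cv) d <<- rbind(d, diagRow("error", key, m))
    for (m in ch@mutate) {
      checkExpr(m$expr, key)
      if (length(ch@classLabels)) {
        fi <- match(m$from, ch@stateNames); ti <- match(m$to, ch@stateNames)
        if (!is.na(fi) && !is.na(ti) &&
            !identical(ch@stateTokens[fi, ], ch@stateTokens[ti, ]) &&
            ch@stateClass[fi] != ch@stateClass[ti])
          d <<- rbind(d, diagRow("warning", key, paste0(
            "simultaneous token and class change: ", m$from, " -> ", m$to)))
      }
    }
    for (nm in names(ch@initial)) checkExpr(ch@initial[[nm]], key)
  }
  for (key in names(g@chains)) {
    ch <- g@chains[[key]]
    if (is(ch, "HybridChain")) {
      hv <- validObject(ch, test = TRUE)
      if (is.character(hv))
        for (m in hv) d <- rbind(d, diagRow("error", key, m))
      for (nm in names(ch@components)) eachPlain(ch@components[[nm]],
                                                 paste0(key, ":", nm))
      eachPlain(ch@default, paste0(key, ":default"))
    } else eachPlain(ch, key)
  }
  stars <- character(0)
  for (r in g@rules) {
    where <- paste0(r$lhs, " rule")
    if (r$kind == "emission") {
      if (!(r$chain %in% names(g@chains)))
        d <- rbind(d, diagRow("error", where, paste0(
          "emission references unknown chain: ", r$chain)))
      stars <- c(stars, r$nxt)
    } else {
      checkExpr(r$prob, where)
      refs <- if (r$kind == "end") character(0) else r$to
      for (nt in refs)
        if (!(nt %in% g@nonterms))
          d <- rbind(d, diagRow("error", where, paste0(
            "rule references undeclared nonterminal: ", nt)))
    }
  }
  for (r in g@rules)
    if (r$kind == "emission") {
      hasReturn <- any(vapply(g@rules, function(q)
        q$kind %in% c("return", "transition", "end") && q$lhs == r$nxt,
        logical(1)))
      outFromLhs <- any(vapply(g@rules, function(q)
        q$kind %in% c("transition", "end") && q$lhs == r$lhs, logical(1)))
      if (!hasReturn && !outFromLhs)
        d <- rbind(d, diagRow("error", paste0(r$lhs, " rule"), paste0(
          "emission has no matching return/continuation for ", r$nxt)))
    }
  if (!(g@start %in% g@nonterms))
    d <- rbind(d, diagRow("error", "grammar", "start symbol not declared"))
  if (nrow(d) == 0L) emptyDiag else d
}

#' @describeIn validateGrammar \code{TRUE} when no error-severity
#'   diagnostics are present.
#' @export
isValidGrammar <- function(g) {
  d <- validateGrammar(g)
  !any(d$severity == "error")
}

#' Classify a grammar as phylo-HMM or phylo-SCFG
#'
#' A grammar is a phylo-HMM when its rules contain no bifurcations and every
#' emission places all its pseudoterminals on one fixed side of the
#' nonterminal; otherwise it is a phylo-SCFG.
#'
#' @param g a validated \code{\link{Grammar}}.
#' @return \code{"phylo-HMM"} or \code{"phylo-SCFG"}.
#' @export
classifyGrammar <- function(g) {
  sides <- character(0)
  for (r in g@rules) {
    if (r$kind == "bifurcation") return("phylo-SCFG")
    if (r$kind == "emission") {
      if (r$left > 0L && r$right > 0L) return("phylo-SCFG")
      sides <- c(sides, if (r$left > 0L) "left" else "right")
    }
  }
  if (length(unique(sides)) > 1L) return("phylo-SCFG")
  "phylo-HMM"
}
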