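## Parametric continuous-time Markov chains over token tuples, optionally
## augmented with hidden classes, and their numeric instantiation.

#' Parameter set of a grammar
#'
#' Holds the free rate parameters (nonnegative reals), the probability
#' groups (each normalized to sum to one) and named constants referenced by
#' rate and probability expressions.
#'
#' @slot rates named numeric vector of rate parameters (current/seed values).
#' @slot pgroups named list; each element a named numeric vector summing to 1.
#' @slot consts named numeric vector of untrainable constants.
#' @export
setClass("ParamSet",
  representation(rates = "numeric", pgroups = "list", consts = "numeric"),
  prototype(rates = setNames(numeric(0), character(0)), pgroups = list(),
            consts = setNames(numeric(0), character(0))))

setValidity("ParamSet", function(object) {
  msgs <- character(0)
  if (length(object@rates) && (is.null(names(object@rates)) ||
                               any(!nzchar(names(object@rates)))))
    msgs <- c(msgs, "rate parameters must be named")
  if (any(object@rates < 0)) msgs <- c(msgs, "rate parameters must be >= 0")
  for (g in names(object@pgroups)) {
    p <- object@pgroups[[g]]
    if (any(p < 0)) msgs <- c(msgs, paste0("pgroup ", g, " has negative entries"))
    if (abs(sum(p) - 1) > 1e-9)
      msgs <- c(msgs, paste0("pgroup ", g, " does not sum to 1"))
  }
  all <- c(names(object@rates), unlist(lapply(object@pgroups, names)),
           names(object@consts))
  if (anyDuplicated(all))
    msgs <- c(msgs, paste0("duplicate parameter name(s): ",
                           paste(unique(all[duplicated(all)]), collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ParamSet constructor.  Probability groups whose seeds do not
#'   sum to one are renormalized with a warning.
#' @param rates,pgroups,consts see slots.
#' @export
paramSet <- function(rates = numeric(0), pgroups = list(),
                     consts = numeric(0)) {
  rates <- unlist(rates); if (is.null(rates)) rates <- numeric(0)
  consts <- unlist(consts); if (is.null(consts)) consts <- numeric(0)
  pgroups <- lapply(pgroups, unlist)
  for (g in names(pgroups)) {
    s <- sum(pgroups[[g]])
    if (abs(s - 1) > 1e-9) {
      if (s <= 0) stop("pgroup ", g, " not normalizable (sum ", s, ")",
                       call. = FALSE)
      warning("pgroup ", g, " seeds sum to ", format(s),
              "; renormalizing to 1", call. = FALSE)
      pgroups[[g]] <- pgroups[[g]] / s
    }
  }
  new("ParamSet", rates = rates, pgroups = pgroups, consts = consts)
}

#' @describeIn ParamSet names of the free (trainable) parameters: the rates
#'   plus all probability-group members.
#' @param p a \code{ParamSet}.
#' @export
freeParams <- function(p) {
  c(names(p@rates), unlist(lapply(p@pgroups, names), use.names = FALSE))
}

#' @describeIn ParamSet numeric value of a named parameter or constant.
#' @param name parameter name.
#' @export
paramValue <- function(p, name) {
  if (name %in% names(p@rates)) return(unname(p@rates[[name]]))
  for (g in p@pgroups) if (name %in% names(g)) return(unname(g[[name]]))
  if (name %in% names(p@consts)) return(unname(p@consts[[name]]))
  stop("unbound parameter: ", name, call. = FALSE)
}

#' @describeIn ParamSet merge several parameter sets (later sets win on
#'   name conflicts).
#' @param ... \code{ParamSet} objects.
#' @export
mergeParams <- function(...) {
  sets <- list(...)
  rates <- numeric(0); pg <- list(); consts <- numeric(0)
  for (s in sets) {
    rates[names(s@rates)] <- s@rates
    for (g in names(s@pgroups)) pg[[g]] <- s@pgroups[[g]]
    consts[names(s@consts)] <- s@consts
  }
  new("ParamSet", rates = rates, pgroups = pg, consts = consts)
}

## Evaluate a product expression (character vector of factors, each a
## parameter name or numeric literal, possibly an exact rational "p/q").
evalExpr <- function(factors, params) {
  v <- 1
  for (f in factors) {
    x <- atomNumber(f)
    if (is.na(x)) x <- paramValue(params, f)
    v <- v * x
  }
  v
}

#' Substitution chain over token tuples
#'
#' A parametric CTMC whose states are tuples of alphabet tokens (arity 1 for
#' single columns, 2 for paired columns, 3 for codon triplets), optionally
#' crossed with a hidden class label (e.g. slow/fast substitution mode,
#' annotated through a Stockholm \code{#=GR} row).  Transition rates and the
#' initial distribution are products of named parameters and numeric
#' literals; unlisted transitions have rate zero and diagonal entries are
#' derived as negative row sums at instantiation.
#'
#' States are ordered token-major, class-minor (token tuples enumerate with
#' the last position fastest), giving a deterministic index map.
#'
#' @slot alphabet the \code{\link{Alphabet}}.
#' @slot terminals pseudoterminal names, one per tuple position (length =
#'   arity).
#' @slot classRow Stockholm \code{#=GR} tag for the hidden class
#'   (\code{NA} if the chain has no hidden class).
#' @slot classLabels hidden-class labels (empty if none).
#' @slot stateTokens character matrix (states x arity) of tokens.
#' @slot stateClass per-state class label ("" if none).
#' @slot stateNames unique state names, \code{tokens[~class]}.
#' @slot initial named list: state name -> factor vector (probability
#'   expression).  Empty means "use the stationary distribution if the
#'   instantiated generator is irreducible, else uniform".
#' @slot mutate list of entries \code{list(from=, to=, expr=)}.
#' @slot params \code{\link{ParamSet}} of seed values for the parameters the
#'   chain's expressions reference.
#' @export
setClass("Chain",
  representation(alphabet = "Alphabet", terminals = "character",
                 classRow = "character", classLabels = "character",
                 stateTokens = "matrix", stateClass = "character",
                 stateNames = "character", initial = "list",
                 mutate = "list", params = "ParamSet"))

setValidity("Chain", function(object) {
  msgs <- character(0)
  arity <- length(object@terminals)
  if (arity < 1L) msgs <- c(msgs, "chain needs at least one pseudoterminal")
  if (ncol(object@stateTokens) != arity)
    msgs <- c(msgs, "stateTokens arity does not match the pseudoterminals")
  if (!all(object@stateTokens %in% object@alphabet@tokens))
    msgs <- c(msgs, "state tokens outside the alphabet")
  nclass <- max(1L, length(object@classLabels))
  maxStates <- length(object@alphabet@tokens)^arity * nclass
  if (nrow(object@stateTokens) > maxStates)
    msgs <- c(msgs, "more states than (alphabet size)^arity x classes")
  if (length(object@classLabels) &&
      !all(object@stateClass %in% object@classLabels))
    msgs <- c(msgs, "state class labels outside the declared label set")
  if (anyDuplicated(object@stateNames))
    msgs <- c(msgs, "duplicate state names")
  for (m in object@mutate) {
    if (identical(m$from, m$to))
      msgs <- c(msgs, paste0("mutate entry with from == to: ", m$from))
    if (!(m$from %in% object@stateNames) || !(m$to %in% object@stateNames))
      msgs <- c(msgs, paste0("mutate entry references unknown state: ",
                             m$from, " -> ", m$to))
  }
  if (length(msgs)) msgs else TRUE
})

chainStateName <- function(tokens, class = "") {
  base <- paste(tokens, collapse = "")
  if (nzchar(class)) paste0(base, "~", class) else base
}

#' @describeIn Chain constructor.  When \code{stateTokens} is \code{NULL}
#'   the full product space (alphabet^arity x classes) is enumerated.
#' @param alphabet,terminals,classRow,classLabels,stateTokens,initial,mutate,params
#'   see slots; \code{mutate} entries are \code{list(from, to, expr)}.
#' @export
makeChain <- function(alphabet, terminals, classRow = NA_character_,
                      classLabels = character(0), stateTokens = NULL,
                      initial = list(), mutate = list(),
                      params = paramSet()) {
  arity <- length(terminals)
  if (is.null(stateTokens)) {
    grids <- rev(rep(list(alphabet@tokens), arity))
    g <- do.call(expand.grid, c(grids, list(stringsAsFactors = FALSE)))
    stateTokens <- as.matrix(g[, rev(seq_len(arity)), drop = FALSE])
    dimnames(stateTokens) <- NULL
  }
  stateTokens <- as.matrix(stateTokens)
  nclass <- length(classLabels)
  if (nclass > 0L) {
    idx <- rep(seq_len(nrow(stateTokens)), each = nclass)
    stateClass <- rep(classLabels, times = nrow(stateTokens))
    stateTokens <- stateTokens[idx, , drop = FALSE]
  } else {
    stateClass <- rep("", nrow(stateTokens))
  }
  stateNames <- vapply(seq_len(nrow(stateTokens)), function(i)
    chainStateName(stateTokens[i, ], stateClass[i]), character(1))
  new("Chain", alphabet = alphabet, terminals = terminals,
      classRow = classRow, classLabels = classLabels,
      stateTokens = stateTokens, stateClass = stateClass,
      stateNames = stateNames, initial = initial, mutate = mutate,
      params = params)
}

#' @describeIn Chain number of states.
#' @param x a \code{Chain}.
#' @export
nStates <- function(x) length(x@stateNames)

#' @describeIn Chain tuple arity (number of emitted columns).
#' @export
chainArity <- function(x) {
  if (is(x, "HybridChain")) return(length(x@default@terminals))
  length(x@terminals)
}

setMethod("show", "Chain", function(object) {
  cat("Chain <", paste(object@terminals, collapse = " "), ">: ",
      nStates(object), " states (arity ", length(object@terminals),
      if (length(object@classLabels))
        paste0(", classes ", paste(object@classLabels, collapse = "/"))
      else "", "), ",
      length(object@mutate), " mutate entries\n", sep = "")
})

#' @describeIn Chain append a factor (parameter name or numeric literal,
#'   as a string) to every mutate-entry expression: the scaled chain used
#'   by rate-multiplier HMMs.
#' @param factor scaling factor (parameter name or numeric literal).
#' @export
scaleChain <- function(chain, factor) {
  chain@mutate <- lapply(chain@mutate, function(m) {
    m$expr <- c(m$expr, factor); m
  })
  chain
}

#' Lineage-specific (hybrid) chain
#'
#' A pseudoterminal whose substitution process differs across tree branches:
#' each branch resolves to the component whose name equals the branch's
#' child-node label, falling back to the default chain.  All components must
#' share the default's alphabet, arity and class labels.
#'
#' @slot terminals pseudoterminal names.
#' @slot selector description of the selecting key (node labels).
#' @slot components named list of \code{Chain}s, keyed by node label.
#' @slot default the fallback \code{Chain}.
#' @export
setClass("HybridChain",
  representation(terminals = "character", selector = "character",
                 components = "list", default = "Chain"))

setValidity("HybridChain", function(object) {
  msgs <- character(0)
  d <- object@default
  for (nm in names(object@components)) {
    cc <- object@components[[nm]]
    if (!is(cc, "Chain")) { msgs <- c(msgs, "components must be Chains"); next }
    if (!identical(cc@alphabet@tokens, d@alphabet@tokens))
      msgs <- c(msgs, paste0("component ", nm, ": different alphabet"))
    if (length(cc@terminals) != length(d@terminals))
      msgs <- c(msgs, paste0("component ", nm, ": different arity"))
    if (!identical(cc@classLabels, d@classLabels))
      msgs <- c(msgs, paste0("component ", nm, ": different class labels"))
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn HybridChain constructor.
#' @param terminals,components,default,selector see slots.
#' @export
hybridChain <- function(terminals, components, default,
                        selector = "node-label") {
  new("HybridChain", terminals = terminals, selector = selector,
      components = components, default = default)
}

## Resolve the component a branch uses, by its child-node label.
resolveComponent <- function(chain, childLabel) {
  if (!is(chain, "HybridChain")) return(chain)
  if (childLabel %in% names(chain@components))
    chain@components[[childLabel]]
  else chain@default
}

setMethod("show", "HybridChain", function(object) {
  cat("HybridChain <", paste(object@terminals, collapse = " "), ">: ",
      length(object@components), " branch components + default (",
      nStates(object@default), " states)\n", sep = "")
})

#' Instantiated rate matrix
#'
#' A numeric generator \code{Q} over a chain's state space, with initial
#' distribution \code{pi}.  Off-diagonal entries are nonnegative and each
#' diagonal entry is the negative sum of its row's off-diagonal entries.
#'
#' @slot Q numeric generator matrix (states x states, dimnames = state
#'   names).
#' @slot pi initial distribution (sums to 1).
#' @slot states state names.
#' @export
setClass("RateMatrix",
  representation(Q = "matrix", pi = "numeric", states = "character"))

setValidity("RateMatrix", function(object) {
  msgs <- character(0)
  Q <- object@Q
  if (nrow(Q) != ncol(Q)) msgs <- c(msgs, "Q must be square")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) msgs <- c(msgs, "negative off-diagonal rate")
  if (any(abs(rowSums(Q)) > 1e-8)) msgs <- c(msgs, "rows do not sum to 0")
  if (abs(sum(object@pi) - 1) > 1e-9)
    msgs <- c(msgs, "initial distribution does not sum to 1")
  if (length(object@states) != nrow(Q))
    msgs <- c(msgs, "state names do not match Q")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "RateMatrix", function(object) {
  cat("RateMatrix: ", nrow(object@Q), " states, ",
      sum(object@Q > 0), " nonzero off-diagonal entries\n", sep = "")
})

## Is the sparsity graph of Q strongly connected?
isIrreducible <- function(Q) {
  n <- nrow(Q)
  if (n == 1L) return(TRUE)
  A <- (abs(Q) > 0); diag(A) <- TRUE
  reach <- function(adj) {
    seen <- c(TRUE, rep(FALSE, n - 1L))
    frontier <- 1L
    while (length(frontier)) {
      nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    all(seen)
  }
  reach(A) && reach(t(A))
}

## Stationary distribution of an irreducible generator: the null vector of
## t(Q), taken from the SVD (robust to near-zero generators).
stationaryDistribution <- function(Q) {
  n <- nrow(Q)
  sv <- svd(t(Q))
  pi <- sv$v[, n]
  if (sum(pi) < 0) pi <- -pi
  pi[pi < 0 & pi > -1e-9] <- 0
  if (any(pi < 0)) return(rep(1 / n, n))
  pi / sum(pi)
}

#' Instantiate a chain's numeric rate matrix
#'
#' Evaluates every mutate-entry expression (a product of parameter values
#' and literals) under a parameter set, fills the diagonal as negative row
#' sums, and resolves the initial distribution: declared initial entries are
#' evaluated and normalized; a chain with no initial entries gets the
#' stationary distribution of its generator when irreducible, else uniform.
#'
#' @param chain a \code{\link{Chain}}.
#' @param params a \code{\link{ParamSet}} binding every referenced
#'   parameter; defaults to the chain's own seed values.
#' @return a \code{\link{RateMatrix}}.
#' @export
instantiateMatrix <- function(chain, params = chain@params) {
  n <- nStates(chain)
  st <- chain@stateNames
  Q <- matrix(0, n, n, dimnames = list(st, st))
  for (m in chain@mutate) {
    Q[m$from, m$to] <- Q[m$from, m$to] + evalExpr(m$expr, params)
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  if (length(chain@initial)) {
    pi <- setNames(numeric(n), st)
    for (nm in names(chain@initial))
      pi[nm] <- evalExpr(chain@initial[[nm]], params)
    s <- sum(pi)
    if (s <= 0) stop("initial distribution not normalizable", call. = FALSE)
    pi <- pi / s
  } else if (isIrreducible(Q)) {
    pi <- stationaryDistribution(Q)
  } else {
    pi <- rep(1 / n, n)
  }
  new("RateMatrix", Q = Q, pi = unname(pi), states = st)
}
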