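## Native constructors for the built-in models: Jukes-Cantor, the latent
## slow/fast rate-class chain, discrete-Gamma rate multipliers, the
## rate-multiplier phylo-HMM, the lineage-specific subtree-scaling
## phylo-HMM, and the Nielsen-Yang codon model.

#' Jukes-Cantor DNA chain
#'
#' The maximally symmetric DNA substitution model: every off-diagonal rate
#' equals the single parameter u.  With u = 1/3 the stationary process
#' performs one substitution per unit time on average.
#'
#' @param u substitution rate parameter (> 0), seed value for training.
#' @param terminal pseudoterminal name.
#' @param rateName name of the rate parameter.
#' @return a \code{\link{Chain}}.
#' @export
jukesCantor <- function(u = 1, terminal = "JC", rateName = "u") {
  if (u <= 0) stop("u must be > 0", call. = FALSE)
  alph <- dnaAlphabet()
  mut <- list()
  for (t1 in alph@tokens) for (t2 in alph@tokens)
    if (t1 != t2)
      mut[[length(mut) + 1L]] <- list(from = t1, to = t2, expr = rateName)
  makeChain(alph, terminal, mutate = mut,
            params = paramSet(rates = setNames(u, rateName)))
}

#' Latent slow/fast rate-class chain
#'
#' A DNA chain augmented with a hidden class in \{s, f\}: substitutions
#' within a class follow Jukes-Cantor scaled by the class rate (s slow, f
#' fast), and the class flips with rates r_sf and r_fs; token and class
#' never change simultaneously.  The class is annotated through the
#' Stockholm \code{#=GR} row \code{CLASS}.
#'
#' @param s,f within-class rate scalers (slow, fast).
#' @param r_sf,r_fs class switch rates (slow->fast, fast->slow).
#' @param u the underlying substitution rate.
#' @param terminal pseudoterminal name.
#' @return an 8-state \code{\link{Chain}}.
#' @export
raserChain <- function(s = 0.1, f = 2.0, r_sf = 0.01, r_fs = 0.01, u = 1.0,
                       terminal = "RASER") {
  if (any(c(s, f, r_sf, r_fs, u) < 0))
    stop("rates must be >= 0", call. = FALSE)
  alph <- dnaAlphabet()
  mut <- list()
  for (c1 in c("s", "f")) for (c2 in c("s", "f"))
    for (t1 in alph@tokens) for (t2 in alph@tokens) {
      if (c1 == c2 && t1 != t2)
        mut[[length(mut) + 1L]] <- list(
          from = chainStateName(t1, c1), to = chainStateName(t2, c2),
          expr = c("u", c1))
      else if (c1 != c2 && t1 == t2)
        mut[[length(mut) + 1L]] <- list(
          from = chainStateName(t1, c1), to = chainStateName(t2, c2),
          expr = paste0("r_", c1, c2))
    }
  makeChain(alph, terminal, classRow = "CLASS", classLabels = c("s", "f"),
            mutate = mut,
            params = paramSet(rates = c(s = s, f = f, r_sf = r_sf,
                                        r_fs = r_fs, u = u)))
}

#' Discrete-Gamma rate multipliers
#'
#' K rates summarizing a Gamma(shape, mean 1) distribution by equal
#' probability bins, each rate the mean of the distribution within its bin
#' (computed from the incomplete-gamma identity, so the rates average
#' exactly 1 — required for their role as rate multipliers).
#'
#' @param shape Gamma shape parameter (> 0); small values = strong rate
#'   heterogeneity.
#' @param K number of rate classes (>= 1).
#' @return numeric vector of K rates with mean 1.
#' @export
discreteGammaRates <- function(shape, K) {
  if (shape <= 0) stop("shape must be > 0", call. = FALSE)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  bounds <- stats::qgamma(seq(0, 1, length.out = K + 1L), shape = shape,
                          rate = shape)
  ## E[X; a<X<b] for Gamma(shape, rate=shape) = F_{shape+1}(b) - F_{shape+1}(a)
  cdf1 <- stats::pgamma(bounds, shape = shape + 1, rate = shape)
  K * diff(cdf1)
}

#' Rate-multiplier phylo-HMM
#'
#' An HMM over K emitting nonterminals "1".."K" sharing one substitution
#' model, nonterminal k scaling it by the rate parameter r_k (seeded from
#' \code{rates}, e.g. \code{\link{discreteGammaRates}} quantile means).
#' Transitions: start -> k with probability 1/K; self-transition stayProb;
#' k -> k' with probability leaveProb/(K-1); every nonterminal may end with
#' weight 1 (the alignment length decides when).  stayProb and leaveProb
#' form a probability group renormalized during training.
#'
#' @param K number of emitting nonterminals.
#' @param baseChain the shared substitution \code{\link{Chain}}.
#' @param rates length-K numeric seeds for the rate multipliers r_1..r_K.
#' @param stayProb self-transition probability.
#' @param name grammar name.
#' @return a phylo-HMM \code{\link{Grammar}}.
#' @export
phastconsHmm <- function(K = 3L, baseChain = jukesCantor(),
                         rates = rep(1, K), stayProb = 0.9,
                         name = "rate-multiplier-hmm") {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (length(rates) != K) stop("need K rate seeds", call. = FALSE)
  if (stayProb < 0 || stayProb > 1) stop("stayProb must be in [0,1]",
                                         call. = FALSE)
  if (K == 1L && stayProb < 1) {
    warning("K = 1 leaves the leave probability with no destination; ",
            "forcing stayProb = 1", call. = FALSE)
    stayProb <- 1
  }
  chains <- list()
  rules <- list()
  ann <- emptyAnnotations()
  rateNames <- paste0("r_", seq_len(K))
  for (k in seq_len(K)) {
    ch <- baseChain
    ch@terminals <- paste0("chain_", k)
    ch <- scaleChain(ch, rateNames[k])
    chains[[k]] <- ch
    nt <- as.character(k)
    rules <- c(rules, list(
      list(lhs = "start", rhs = nt,
           prob = formatMacroNumber(ratCanon(1, K))),
      list(lhs = nt, rhs = character(0), prob = "1"),
      list(lhs = nt, rhs = c(paste0("chain_", k), paste0(nt, "*"))),
      list(lhs = paste0(nt, "*"), rhs = nt)))
    for (k2 in seq_len(K)) {
      nt2 <- as.character(k2)
      pr <- if (k == k2) "stayProb" else
        c("leaveProb", formatMacroNumber(ratCanon(1, K - 1L)))
      rules <- c(rules, list(list(lhs = nt, rhs = nt2, prob = pr)))
    }
    ann <- rbind(ann, data.frame(nonterm = nt, row = "RATE",
                                 label = substr(nt, 1L, 1L),
                                 stringsAsFactors = FALSE))
  }
  params <- mergeParams(
    baseChain@params,
    paramSet(rates = setNames(rates, rateNames),
             pgroups = list(trans = c(stayProb = stayProb,
                                      leaveProb = 1 - stayProb))))
  makeGrammar(name, baseChain@alphabet, chains, rules, params,
              start = "start", annotations = ann)
}

#' Lineage-specific subtree-scaling phylo-HMM
#'
#' One emitting nonterminal per tree node plus a neutral background
#' nonterminal.  Node v's substitution process is a hybrid chain scaling
#' every branch in the subtree rooted at v (each branch named by its child
#' node) by \code{slowScale}, leaving all other branches at the base rate —
#' regions generated by v's nonterminal show lineage-specific selection
#' below v.  Transition structure follows \code{\link{phastconsHmm}} over
#' the node nonterminals plus the background.
#'
#' @param tree a \code{\link{PhyloTree}} (unlabeled internal nodes are
#'   auto-labeled deterministically).
#' @param baseChain neutral substitution \code{\link{Chain}}.
#' @param slowScale rate multiplier (> 0) applied below the focal node.
#' @param stayProb self-transition probability.
#' @param name grammar name.
#' @return a phylo-HMM \code{\link{Grammar}} with one hybrid chain per
#'   tree node.
#' @export
dlessHmm <- function(tree, baseChain = jukesCantor(), slowScale = 0.1,
                     stayProb = 0.9, name = "lineage-hmm") {
  if (slowScale <= 0) stop("slowScale must be > 0", call. = FALSE)
  nodes <- treeNodeLabels(tree)
  slow <- scaleChain(baseChain, formatNum(slowScale))
  slow@terminals <- "slowBase"
  base <- baseChain
  base@terminals <- "base"
  states <- c("bg", nodes)
  K <- length(states)
  chains <- list()
  rules <- list()
  ann <- emptyAnnotations()
  for (k in seq_along(states)) {
    nt <- states[k]
    if (nt == "bg") {
      ch <- baseChain
      ch@terminals <- "chain_bg"
      chains[[length(chains) + 1L]] <- ch
      term <- "chain_bg"
    } else {
      scaled <- subtreeNodeLabels(tree, nt)
      scaled <- setdiff(scaled, treeRootLabel(tree))  # root has no branch
      comps <- setNames(rep(list(slow), length(scaled)), scaled)
      term <- paste0("chain_", nt)
      chains[[length(chains) + 1L]] <-
        hybridChain(term, comps, base, selector = "node-label")
    }
    rules <- c(rules, list(
      list(lhs = "start", rhs = nt,
           prob = formatMacroNumber(ratCanon(1, K))),
      list(lhs = nt, rhs = character(0), prob = "1"),
      list(lhs = nt, rhs = c(term, paste0(nt, "*"))),
      list(lhs = paste0(nt, "*"), rhs = nt)))
    for (nt2 in states) {
      pr <- if (nt == nt2) "stayProb" else
        c("leaveProb", formatMacroNumber(ratCanon(1, K - 1L)))
      rules <- c(rules, list(list(lhs = nt, rhs = nt2, prob = pr)))
    }
    ann <- rbind(ann, data.frame(
      nonterm = nt, row = "NODE",
      label = if (nt == "bg") "." else substr(nt, nchar(nt), nchar(nt)),
      stringsAsFactors = FALSE))
  }
  params <- mergeParams(
    baseChain@params,
    paramSet(pgroups = list(trans = c(stayProb = stayProb,
                                      leaveProb = 1 - stayProb))))
  makeGrammar(name, baseChain@alphabet, chains, rules, params,
              start = "start", annotations = ann)
}

#' Classify the difference between two codons
#'
#' The "type" of a codon pair under a genetic code: how many nucleotide
#' positions differ, whether the single change (if any) is a transition
#' (a<->g, c<->t) or transversion, and whether it is synonymous.
#'
#' @param codon1,codon2 lowercase 3-letter codons.
#' @param code genetic code table (see \code{\link{senseCodons}}).
#' @return list with \code{ndiff}, \code{transition} (logical or NA),
#'   \code{synonymous} (logical or NA), \code{pos} (differing position or
#'   NA).
#' @export
codonPairType <- function(codon1, codon2,
                          code = Biostrings::getGeneticCode("1")) {
  a <- strsplit(codon1, "")[[1L]]
  b <- strsplit(codon2, "")[[1L]]
  diff <- which(a != b)
  if (length(diff) != 1L)
    return(list(ndiff = length(diff), transition = NA, synonymous = NA,
                pos = NA_integer_))
  pair <- sort(c(a[diff], b[diff]))
  transition <- identical(pair, c("a", "g")) || identical(pair, c("c", "t"))
  synonymous <- code[[toupper(codon1)]] == code[[toupper(codon2)]]
  list(ndiff = 1L, transition = transition, synonymous = synonymous,
       pos = diff)
}

#' Nielsen-Yang codon substitution chain
#'
#' The codon model with transition/transversion bias and selection: the
#' rate from codon i to codon j is 0 when the codons differ at more than
#' one nucleotide position, and otherwise pi_j x kappa^[transition] x
#' omega^[nonsynonymous], with synonymy judged by the supplied genetic
#' code (pluggable, e.g. the vertebrate mitochondrial code).  Stop codons
#' are excluded, giving 61 states under the standard code.  The chain is
#' reversible: pi_i q_ij = pi_j q_ji.
#'
#' @param code genetic code table (see \code{\link{senseCodons}}).
#' @param kappa transition/transversion rate ratio (>= 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi codon frequencies over the sense codons (named or in
#'   \code{senseCodons(code)} order); default uniform.
#' @param normalize if \code{TRUE}, scale the generator so the expected
#'   substitution rate at stationarity is one per codon site.
#' @param terminals the three pseudoterminal names (codon positions).
#' @return a \code{\link{Chain}} over codon-triplet states.
#' @export
nielsenYang <- function(code = Biostrings::getGeneticCode("1"), kappa = 2,
                        omega = 0.5, pi = NULL, normalize = FALSE,
                        terminals = c("COD1", "COD2", "COD3")) {
  if (kappa < 0 || omega < 0) stop("kappa and omega must be >= 0",
                                   call. = FALSE)
  codons <- senseCodons(code)
  n <- length(codons)
  if (is.null(pi)) pi <- rep(1 / n, n)
  if (!is.null(names(pi))) pi <- pi[codons]
  if (length(pi) != n || any(is.na(pi)) || any(pi < 0))
    stop("pi must cover the sense codons with nonnegative values",
         call. = FALSE)
  if (abs(sum(pi) - 1) > 1e-6) stop("pi must sum to 1", call. = FALSE)
  pi <- pi / sum(pi)
  names(pi) <- codons
  scale <- 1
  ratesOf <- function() {
    mut <- list()
    for (i in codons) for (j in codons) {
      if (i == j) next
      ty <- codonPairType(i, j, code)
      if (ty$ndiff != 1L) next
      rate <- pi[[j]] * scale
      if (ty$transition) rate <- rate * kappa
      if (!ty$synonymous) rate <- rate * omega
      if (rate == 0) next
      mut[[length(mut) + 1L]] <- list(from = i, to = j,
                                      expr = formatNum(rate))
    }
    mut
  }
  buildChain <- function() {
    stateTokens <- do.call(rbind, strsplit(codons, ""))
    init <- setNames(lapply(pi, formatNum), codons)
    makeChain(alphabet("DNA", c("a", "c", "g", "t")), terminals,
              stateTokens = stateTokens, initial = init,
              mutate = ratesOf(), params = paramSet())
  }
  ch <- buildChain()
  if (normalize) {
    rm <- instantiateMatrix(ch, paramSet())
    rate <- -sum(rm@pi * diag(rm@Q))
    if (rate > 0) {
      scale <- 1 / rate
      ch <- buildChain()
    }
  }
  ch
}

#' Empirical codon frequencies from an alignment
#'
#' Counts in-frame codons over all rows (columns 1-3, 4-6, ...), ignoring
#' codons containing gaps, wildcards or stop codons, with one pseudocount
#' per sense codon.
#'
#' @param aln a \code{StockholmAlignment} or named character vector of
#'   rows.
#' @param code genetic code table.
#' @return named frequency vector over \code{senseCodons(code)}.
#' @export
codonFrequencies <- function(aln, code = Biostrings::getGeneticCode("1")) {
  rows <- asRowMatrix(aln)
  codons <- senseCodons(code)
  counts <- setNames(rep(1, length(codons)), codons)
  L <- ncol(rows) - ncol(rows) %% 3L
  if (L >= 3L) {
    for (r in seq_len(nrow(rows))) {
      for (s in seq(1L, L - 2L, by = 3L)) {
        cod <- paste(rows[r, s:(s + 2L)], collapse = "")
        if (cod %in% codons) counts[cod] <- counts[cod] + 1
      }
    }
  }
  counts / sum(counts)
}
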