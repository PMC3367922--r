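# Shared fixtures: trees, a toy pair (phylo-SCFG) grammar, listing text.

tree4 <- function() parseNewick(
  "((A:0.3,B:0.3)n1:0.2,(C:0.3,D:0.3)n2:0.2)root;")

tree3 <- function() parseNewick("((A:0.1,B:0.2)n1:0.3,C:0.4)root;")

grammarFile <- function(name)
  system.file("extdata", paste0(name, ".eg"), package = "phygram")

# Random small tree over `n` leaves with exponential branch lengths.
randomTree <- function(n, labels = LETTERS[seq_len(n)]) {
  phy <- ape::rtree(n, tip.label = labels,
                    br = function(k) stats::rexp(k, 4) + 0.02)
  phyloTree(phy)
}

# Pair + unpaired toy phylo-SCFG:
#   start -> S;  S -> P | U | E;
#   P emits a column pair, U a single column, E ends.
toyPairGrammar <- function(pPair = 0.3, pUn = 0.4, pEnd = 0.3) {
  alph <- dnaAlphabet()
  toks <- alphabetTokens(alph)
  pairs2 <- sort(as.vector(outer(toks, toks, paste0)))
  pairMut <- list()
  for (s1 in pairs2) for (s2 in pairs2) {
    if (s1 == s2) next
    if (sum(strsplit(s1, "")[[1]] != strsplit(s2, "")[[1]]) == 1L)
      pairMut[[length(pairMut) + 1L]] <- list(from = s1, to = s2,
                                              expr = "v")
  }
  pc <- makeChain(alph, c("PL", "PR"), mutate = pairMut,
                  params = paramSet(rates = c(v = 1)))
  uc <- jukesCantor(1, terminal = "UC")
  rules <- list(
    list(lhs = "start", rhs = "S", prob = "1"),
    list(lhs = "S", rhs = "P", prob = formatC(pPair)),
    list(lhs = "S", rhs = "U", prob = formatC(pUn)),
    list(lhs = "S", rhs = "E", prob = formatC(pEnd)),
    list(lhs = "P", rhs = c("PL", "P*", "PR")),
    list(lhs = "P*", rhs = "S", prob = "1"),
    list(lhs = "U", rhs = c("UC", "U*")),
    list(lhs = "U*", rhs = "S", prob = "1"),
    list(lhs = "E", rhs = character(0), prob = "1"))
  makeGrammar("toy-pair", alph, list(pc, uc), rules,
              mergeParams(pc@params, uc@params), start = "start")
}

# The shared substitution model of the rate-multiplier HMM listing: one
# named rate parameter per ordered token pair (Q_a_c etc.), all seeded 1.
namedEntryJC <- function(terminal = "QJC") {
  alph <- dnaAlphabet()
  mut <- list()
  rates <- numeric(0)
  for (t1 in alph@tokens) for (t2 in alph@tokens) {
    if (t1 == t2) next
    nm <- paste0("Q_", t1, "_", t2)
    mut[[length(mut) + 1L]] <- list(from = t1, to = t2, expr = nm)
    rates[nm] <- 1
  }
  makeChain(alph, terminal, mutate = mut,
            params = paramSet(rates = rates))
}

# Read the rate-multiplier HMM listing with a different nonterminal count.
phastconsListing <- function(K) {
  txt <- readLines(grammarFile("phastcons"), warn = FALSE)
  sub("\\(&define numNonterms 3\\)",
      sprintf("(&define numNonterms %d)", K), txt)
}

# Order-independent summary for structural grammar comparison.
canonicalGrammarSummary <- function(g) {
  ruleKey <- function(r) {
    v <- evalExpr(r$prob, g@params)
    to <- switch(r$kind,
      end = "",
      emission = paste(r$chain, r$left, r$right, r$nxt),
      paste(r$to, collapse = " "))
    sprintf("%s|%s|%s|%.12g", r$kind, r$lhs, to, v)
  }
  used <- unique(vapply(Filter(function(r) r$kind == "emission", g@rules),
                        function(r) r$chain, character(1)))
  chainsum <- lapply(g@chains[sort(intersect(names(g@chains), used))],
                     function(ch) {
    if (is(ch, "HybridChain")) {
      comps <- lapply(ch@components[order(names(ch@components))],
                      function(cc) instantiateMatrix(cc, g@params)@Q)
      list(kind = "hybrid", comps = comps,
           default = instantiateMatrix(ch@default, g@params)@Q)
    } else {
      rm <- instantiateMatrix(ch, g@params)
      list(kind = "plain", Q = rm@Q, pi = rm@pi,
           classes = ch@classLabels, classRow = ch@classRow)
    }
  })
  pn <- sort(freeParams(g@params))
  list(nonterms = sort(g@nonterms),
       rules = sort(vapply(g@rules, ruleKey, character(1))),
       chains = chainsum,
       params = setNames(vapply(pn, function(n)
         paramValue(g@params, n), numeric(1)), pn))
}
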