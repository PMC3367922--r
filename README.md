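# phygram: phylogenetic grammars in R

`phygram` is an engine for **phylo-grammars** — stochastic grammars
(phylo-HMMs and phylo-SCFGs) whose terminal emissions are multiple-alignment
column tuples evolving on a phylogeny under continuous-time Markov
substitution models. Phylo-grammars unify comparative-genomics analyses that
partition an alignment into regions with different evolutionary dynamics:
conserved-element detection, rate-class segmentation, lineage-specific
selection, codon selection pressure, and RNA structure prediction.

The package is for computational biologists who want to *prototype* such
models rather than hard-code them: a model is either written as a compact
S-expression grammar file with macros, or built from the provided
constructors, and the same inference machinery (likelihood, training,
decoding, simulation) applies to all of them.

## The model

A phylo-grammar generates an alignment in two steps:

1. **Nonterminal transformations.** Starting from the `start` nonterminal,
   production rules are applied until only pseudoterminals remain. If the
   rules contain no bifurcations and every emission puts its pseudoterminals
   on one fixed side of the nonterminal, the grammar is a phylo-HMM;
   otherwise it is a phylo-SCFG (which can model nested pairings, as in RNA
   structure).
2. **Token evolution.** Each pseudoterminal group (a single column, a paired
   column duo, or a codon triplet) draws a root tuple from its chain's
   initial distribution π and evolves it down the tree: branch *b* of length
   *t* transforms states by `exp(Q_b t)`, where `Q` is a parametric rate
   matrix whose entries are products of named parameters
   (e.g. `q(i→j) = u·s` for a slow-class substitution). Hidden classes
   (latent per-column labels such as slow/fast) enlarge the state space;
   *hybrid chains* let `Q_b` differ across branches (lineage-specific
   models). The likelihood of a column sums over ancestral states by
   Felsenstein pruning.

Inference reverses the process: forward–backward (HMM) or inside–outside
(SCFG) dynamic programming gives total likelihoods and per-column
posteriors; Viterbi/CYK gives the single best parse; expectation–maximization
re-estimates rate parameters (from expected substitution counts and wait
times integrated along branches) and probability groups (`pgroup`s,
renormalized from expected rule usages); marginal ancestral reconstruction
returns per-node posteriors whose argmax is the most probable ancestral
state.

Built-in constructors cover the classic model family:

| constructor | model |
|---|---|
| `jukesCantor(u)` | symmetric DNA substitution |
| `raserChain(s, f, r_sf, r_fs, u)` | latent slow/fast rate classes (8 states, 5 parameters) |
| `discreteGammaRates(shape, K)` | K Gamma-quantile rate multipliers, mean 1 |
| `phastconsHmm(K, baseChain, rates, stayProb)` | K-state rate-multiplier phylo-HMM |
| `dlessHmm(tree, baseChain, slowScale, stayProb)` | per-node subtree-scaling (lineage-specific) phylo-HMM |
| `nielsenYang(code, kappa, omega, pi)` | codon selection model, `rate(i→j) = π_j κ^[transition] ω^[nonsyn]`, pluggable genetic code |

Grammar files use a Lisp S-expression dialect with macros
(`&foreach-token`, `&foreach-integer`, `&foreach-node`, `&if`/`&eq`, `&cat`,
exact-rational arithmetic, `&define`, `&include`); see
`inst/extdata/*.eg` for complete examples and `vignettes/phylo-grammars.Rmd`
for the semantics.

## Worked example

Segment an alignment into slow and fast regions with a 2-state
rate-multiplier phylo-HMM, train it on data simulated from itself, and
decode:

```r
library(phygram)

tree <- parseNewick(
  "((human:0.3,chimp:0.3)n1:0.2,(mouse:0.3,rat:0.3)n2:0.2)root;")
g <- phastconsHmm(K = 2, baseChain = jukesCantor(0.3),
                  rates = c(1/3, 3), stayProb = 0.9)
g
#> Grammar 'rate-multiplier-hmm' (phylo-HMM)
#>   alphabet: DNA (4 tokens)
#>   nonterminals: 5 (start: start)
#>   chains: 2; rules: 12 (emission=2, end=2, return=2, transition=6)
#>   free parameters: 5

aln <- simulateAlignment(g, tree, length = 200, seed = 42)
fit <- emTrain(g, aln, tree, maxIter = 10)
round(fit$trace, 2)
#> [1] -1001.97 -1001.66 -1001.66

ann <- annotateAlignment(fit$grammar, aln, tree)
head(ann@gff[, c("type", "start", "end", "score")])
#>   type start end  score
#> 1    2     1  12 0.9025
#> 2    1    13  20 0.9058
#> 3    2    21  27 0.9595
#> 4    1    28  38 0.9830
#> 5    2    39  42 0.9687
#> 6    1    43  45 0.6837

mean(ann@labels == attr(aln, "truth"))
#> [1] 0.945
```

The GFF table lists maximal runs of each decoded nonterminal ("1" = slow,
"2" = fast) in 1-based alignment coordinates with the mean posterior as
score; 94.5% of columns are decoded to their generating state. The same
objects can be written as Stockholm (`writeStockholm`, with `#=GC` state
rows, `#=GR` hidden-class rows and the tree embedded under `#=GF NH`), GFF
(`writeGff`) and WIG (`writeWig`).

The full flow — read Stockholm, expand grammar macros, estimate a
neighbor-joining tree if none is embedded, train, annotate, reconstruct
ancestors — is available as one call (`runPipeline`) and as a command-line
script:

```sh
Rscript inst/scripts/xgram.R -g grammar.eg -l 300 --wig out.wig in.stk > out.stk
Rscript inst/scripts/xgram.R -g grammar.eg -t trained.eg in.stk
```

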