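---
title: "Phylo-grammars: models, semantics and numerical choices"
author: "phygram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylo-grammars: models, semantics and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phygram)
```

# The generative model

A phylo-grammar couples two stochastic processes. The *grammar* layer
rewrites nonterminal symbols by production rules, starting from `start`,
until only pseudoterminals remain; each pseudoterminal group stands for an
alignment column tuple (one column, a paired duo, or a codon triplet). The
*phylo* layer then fills each tuple: a root state is drawn from the emitting
chain's initial distribution and evolved down a rooted tree with branch
lengths in expected substitutions per site; branch $b$ of length $t$ maps
state distributions through $\exp(Q_b t)$.

Chains are *parametric*: each allowed transition carries a product of named
nonnegative parameters and literals, so `(rate u s)` means $q_{ij} = u\,s$.
Hidden classes multiply the token space by a latent label set (e.g. slow
`s` / fast `f`), observable only through inference and exported as Stockholm
`#=GR` rows. Hybrid chains relax the homogeneity assumption: a branch,
identified by its child node's label, can use a different component chain —
the lineage-specific models.

Two structural assumptions matter downstream. First, substitution is the
only process: there is no insertion/deletion model, so gaps in an alignment
are treated as missing data (an indicator of 1 over all states), exactly
like wildcards. Second, the standard chains here (Jukes-Cantor, the
latent-class chain, the codon model) are time-reversible, which makes the
likelihood invariant to root placement; the neighbor-joining tree estimate
therefore roots arbitrarily at its final join.

## Rule semantics

Grammar files declare emissions as
`(transform (from (X)) (to (CHAIN X*)))` with a matching return
`(transform (from (X*)) (to (X)))`. Published grammar listings write the
probabilistic transitions from either the unstarred name (`X`) or the
starred continuation (`X*`). `phygram` accepts both dialects with one
semantics: *an emitting nonterminal emits with probability one upon entry,
and its probabilistic transitions apply after the emission*. Concretely,
the post-emission rule set of `X` is the union of the non-emission rules
written from `X` and the rules written from `X*`; a bare `X* -> X` rule
with probability 1 is treated as structural sugar whenever `X` carries its
own continuation rules, and as a genuine re-emission transition otherwise.

End rules are *unnormalized weights* (the conventional `(prob 1)` on every
end rule): the alignment length, not a length model, decides where the
parse stops, and the dynamic programming normalizes globally. Posteriors
and EM are unaffected by this choice; only absolute likelihood values
would be, and they are compared solely between models scored on the same
data.

# The macro language

The fixed macro vocabulary is: iteration (`&foreach`, `&foreach-token`,
`&foreach-integer`, `&foreach-node`, `&foreach-leaf`, `&foreach-branch`,
plus the list-valued atoms `&TOKENS`, `&NODES`, `&LEAVES`, `&BRANCHES`,
`&COLUMNS`), conditionals (`&if` with string equality `&eq`/`&neq` and
numeric `&numeq`/`&gt`/`&lt`/`&geq`/`&leq`), atom building (`&cat`),
arithmetic (`&+ &- &* &/`), bindings (`&define`) and file inclusion
(`&include`, resolved relative to the including file first, then the
search path). Iteration macros splice one expansion per element into the
enclosing list; an expansion that yields the empty list `()` is discarded,
which is how the `(&if (&eq tok1 tok2) () ...)` idiom skips diagonal
matrix entries. `&if` expands only the branch it selects, so the
untaken branch may contain expressions that would be errors (e.g. a
division by `K - 1` in a single-state model).

Arithmetic is exact-rational whenever all operands are integers or
rationals: `(&/ 1 3)` expands to the atom `1/3`, not `0.333…`, so
probability groups that must sum to one survive expansion without decimal
drift; mixed operands fall back to double precision. Division whose
numerator is still a symbolic parameter name, as in
`(&/leaveProb (&- numNonterms 1))`, expands to the product form
`(leaveProb 1/2)`, consistent with the general product syntax of
`(rate ...)` and `(prob ...)` expressions. The spelled-together form
`&/x` is a tokenizer alias for `(&/ x ...)`. `&eq` compares atom
spellings after expansion — it is meant for tokens and class labels — and
the numeric comparisons are separate macros. One published rate-multiplier
HMM listing declares the pgroup members `stayProb`/`leaveProb` but refers
to `changeProb` in a transition, and carries a misplaced closing
parenthesis in its `&if`; the shipped `inst/extdata/phastcons.eg` uses
`leaveProb` throughout (the two names denote the same parameter) and the
repaired parenthesis, following the accompanying prose.

# Parameters of the built-in models

* `jukesCantor(u)` — `u` is the per-pair substitution rate; `u = 1/3`
  calibrates the chain to one expected substitution per site per unit time,
  which makes branch lengths directly interpretable.
* `raserChain(s = 0.1, f = 2, r_sf = 0.01, r_fs = 0.01, u = 1)` — `s`/`f`
  scale the within-class substitution rate; `r_sf`/`r_fs` are the
  class-switch rates. Defaults are the published seed values. Token and
  class never change in one event.
* `discreteGammaRates(shape, K)` — equal-probability Gamma bins with
  *bin means* (from the incomplete-gamma identity), not quantile
  midpoints: bin means preserve the unit mean exactly, which the
  rate-multiplier role requires.
* `phastconsHmm(K = 3, baseChain, rates, stayProb = 0.9)` — `rates` seed
  the trainable multipliers `r_1..r_K`; `stayProb`/`leaveProb` form a
  pgroup. `K = 1` forces `stayProb = 1` with a warning, since the leave
  mass would have no destination.
* `dlessHmm(tree, baseChain, slowScale, stayProb)` — the simplified
  lineage-specific model: one nonterminal per tree node scaling every
  branch in that node's subtree by the single factor `slowScale`, plus a
  neutral background state. Per-branch gain/loss rates of the full
  published model are out of scope. Unlabeled internal nodes are
  auto-named `node1, node2, …` in preorder so hybrid-chain selectors are
  reproducible.
* `nielsenYang(code, kappa, omega, pi)` — `kappa` is the
  transition/transversion ratio, `omega` the nonsynonymous/synonymous
  ratio, `pi` the codon frequencies (uniform by default;
  `codonFrequencies()` estimates them from in-frame codon counts with one
  pseudocount per sense codon). The generator follows the canonical
  parameterization $q_{ij} = \pi_j \kappa^{[\mathrm{ts}]}
  \omega^{[\mathrm{nonsyn}]}$ for single-nucleotide changes; because the
  original display of these criteria admits an overall normalization, the
  unit-expected-rate scaling is exposed as `normalize = TRUE` rather than
  assumed. The genetic code is a plain 64-entry table
  (`Biostrings::getGeneticCode`), so alternate codes (e.g. vertebrate
  mitochondrial) change both the sense-codon state space and synonymy.

Chains with no declared initial distribution get the stationary
distribution of their instantiated generator when it is irreducible
(the standard convention for reversible models, whose listings omit π),
and the uniform distribution otherwise; initial distributions are not
re-estimated during training.

# Numerical choices

**Matrix exponentials** use the eigendecomposition when the generator is
diagonalizable to machine tolerance (verified by reconstructing $Q$ and by
row-stochasticity of the result), and fall back to scaling-and-squaring
(`Matrix::expm`) otherwise; both paths are tested against each other.
Entries below zero by rounding are clamped.

**Pruning** is vectorized across alignment columns with per-node scaling
(each internal node's partial likelihood matrix is renormalized columnwise
and the log factors accumulated), so megabase-scale alignments cannot
underflow. Distinct column patterns are deduplicated before pruning; with
four taxa there are at most 256 patterns regardless of alignment length.

**HMM recursions** run in log space with exact log-sum-exp; states advance
by their tuple arity, so codon-emitting states consume three columns per
step. **SCFG recursions** run over half-open column spans in log space.
Two normal-form restrictions apply, both satisfied by all built-in and
published model shapes: bifurcation children must each consume at least one
column, and pure transition cycles among nonterminals at the same span are
rejected at compile time — either would otherwise introduce infinite
geometric rule series. The pairing band `-l N` excludes any two-sided
emission whose outermost columns are more than `N` apart; the banded
likelihood is non-decreasing in `N` and reaches the unbanded value at the
alignment length. CYK breaks ties toward the lowest-index rule, making
best parses reproducible.

**EM.** The E-step takes expected rule usages from forward-backward or
inside-outside, and expected substitution counts and state wait times from
per-branch endpoint posteriors integrated along each branch with the
eigendecomposition integral
$\int_0^t P(k,i;s)\,P(j,l;t-s)\,ds$; non-diagonalizable generators fall
back to Simpson quadrature of the same integral. The M-step renormalizes
each pgroup from its usage counts and updates each rate parameter as
(tied event counts) / (tied, factor-weighted wait times). For rates that
appear as products of several parameters this update is one coordinate
sweep, which is not exactly the M-step optimum; monotonicity of the trace
is enforced by geometric backtracking toward the previous parameters, and
training stops if no improving step exists. Parameters driven to zero are
floored at $10^{-6}$ with a warning. Defaults: `tol = 1e-4` relative,
`maxIter = 30`, both settable from the CLI.

**Ancestral reconstruction** is marginal per node and column: the
posterior from the up/down recursion on the tree, whose argmax is by
construction the most probable single state. When a grammar has several
chains, reconstruction conditions on the CYK/Viterbi best parse (each
column uses the chain of its decoded nonterminal); marginalizing over
parses instead would mix chains with incompatible state spaces and is left
as a flagged extension. Hidden-class `#=GR` rows are the per-leaf class
posteriors maximized per column, conditioned the same way.

**Neighbor-joining** input distances are pairwise Jukes-Cantor-corrected
mismatch fractions over shared informative columns (the published
pipeline names the tree estimator but not the distance; JC correction
matches the package's null chain). Saturated pairs are capped, negative
inferred branch lengths are clamped to zero with a warning, and a 2-taxon
matrix splits its single distance evenly across an arbitrary root.

# The simulator and what passing tests mean

`simulateAlignment()` samples a parse (locally normalized rule weights),
draws root tuples from π and evolves them branchwise by sampling from
`exp(Qt)` rows — not event-by-event simulation, which is only used (as
`samplePathCounts()`) to check expected event counts against the
generator's rate. For phylo-HMMs a fixed alignment length is obtained by
conditioning the state path on the target length (end weights dropped until
it is reached); phylo-SCFGs use rejection against a length window, because
their length distribution is structural. Ground truth is written as `#=GC`
(parse) and `#=GR` (classes).

The simulator emulates exactly the generative assumptions above —
substitution-only evolution on a known, fixed tree, homogeneous within the
chain's specification, with independent columns given the parse. Real
alignments violate all of these in places: they contain indels and
alignment error, tree estimates are noisy, and rate variation is continuous
rather than K-class. Tests that pass on simulated data therefore validate
the *inference machinery* (likelihood correctness, estimator consistency,
decoder calibration), not the adequacy of any particular model for real
sequences.

Problem sizes were chosen to make sampling error negligible relative to
the checked tolerances while keeping the whole suite in the minutes range:
enumeration oracles run on trees of 2-4 leaves, chains of 4-8 states and
alignments of up to 6 columns (where exhaustive sums are exact);
parameter-recovery experiments use 5,000 columns for a single substitution
rate (standard error well under the 10% check) and 10,000 columns for a
self-transition probability (binomial error ~0.006 against a 0.05 check);
consistency sweeps use 200-1,000 random fixtures.

# Known limitations

* No indel process; gaps are missing data.
* Tree topology and branch lengths are fixed or NJ-estimated, never
  trained or sampled.
* SCFG rule forms are limited to the normal form above — no pseudoknots,
  no context-sensitive rules, no per-branch rule probabilities.
* The macro language is the fixed vocabulary above; grammar files cannot
  define new functions (the native constructors cover the models that
  would need them, e.g. the codon model's synonymy logic).
* The SCFG span recursion is cubic in alignment length; long alignments
  require the pairing band, and genome-scale screens should be chunked.
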