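Package: phygram
Title: Phylogenetic Grammars: Specification, Inference and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An engine for phylogenetic stochastic grammars (phylo-HMMs and
    phylo-SCFGs) coupling production-rule models of alignment structure to
    continuous-time Markov substitution processes on a phylogeny. Grammars are
    written as S-expressions with a macro language for compact specification of
    repetitively structured models; the package expands macros, instantiates
    parametric rate matrices (including latent-class and lineage-specific
    hybrid chains), computes likelihoods by Felsenstein pruning, trains
    parameters by expectation-maximization, reconstructs marginal ancestral
    states, decodes annotations via forward-backward, inside-outside and CYK
    dynamic programming, simulates annotated alignments, and reads and writes
    Stockholm, Newick, GFF and WIG formats. Built-in constructors cover
    Jukes-Cantor, latent slow/fast rate-class chains, rate-multiplier
    phylo-HMMs with discrete-Gamma rates, lineage-specific subtree-scaling
    phylo-HMMs, and the Nielsen-Yang codon model with pluggable genetic codes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    Matrix,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'sexpr.R'
    'macro.R'
    'alphabet.R'
    'chain.R'
    'grammar.R'
    'models.R'
    'tree.R'
    'likelihood.R'
    'counts.R'
    'inference.R'
    'em.R'
    'stockholm.R'
    'gffwig.R'
    'simulate.R'
    'pipeline.R'
    'phygram-package.R'
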