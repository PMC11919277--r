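Package: convclock
Title: Convergent Molecular Evolution of Circadian Clock Genes and Sleep Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline linking circadian clock gene evolution to
    sleep architecture in mammals. Implements marginal ancestral amino-acid
    reconstruction by the pruning algorithm under empirical substitution
    models (JTT with gene-specific frequencies), Zhang-Kumar detection of
    convergent and parallel substitutions between independent foreground
    lineages with a model-based expected-count null and one-sided Poisson
    test, column-wise scanning for lineage-specific and shared-specific
    substitutions, phylogenetic generalized least squares regression of
    evolutionary rate on sleep traits with maximum-likelihood Pagel's
    lambda, Nei-Gojobori (NG86) dN/dS estimation, and larval zebrafish
    sleep-bout summarization from binned activity traces. Ships
    seed-deterministic synthetic-data generators (sequence evolution along
    trees with optional planted convergence, Brownian-motion traits, codon
    pairs with known omega, activity traces with known bouts) so every
    stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    nlme,
    jsonlite
Config/testthat/edition: 3
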