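Package: gsenrich
Title: Bayesian Enrichment and Prioritization Analysis of GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Model-based enrichment analysis of gene sets and pathways using
    genome-wide association study (GWAS) summary statistics and external
    linkage-disequilibrium (LD) reference panels.  Fits a spike-and-slab
    Bayesian multiple-regression model to single-SNP effect estimates via
    coordinate-ascent variational inference over a hyperparameter grid,
    summarizes the evidence that SNPs near a gene set are enriched for trait
    associations with a Bayes factor, re-weights locus-level association
    probabilities in light of inferred enrichment, and estimates pairwise
    sharing of pathway enrichments between traits.  Includes a banded
    shrinkage LD estimator, a simulation module for benchmarking, and exact
    small-instance enumeration oracles for validating the variational
    approximation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
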