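Package: xwas
Title: Summary-Statistic Proteome- and Transcriptome-Wide Association with
    Colocalization and Chemical Gene-Set Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for gene-level association of genetically predicted
    molecular abundance (protein, transcript, or splicing) with a complex
    trait from GWAS summary statistics, an LD reference panel, and per-gene
    cis-SNP weight models (PWAS/TWAS). Includes permutation-based empirical
    P values, Bayesian colocalization posteriors over the five
    single-causal-variant hypotheses, and weighted Kolmogorov-Smirnov
    gene-set enrichment with a permutation null, as used for chemical-gene
    interaction sets. A synthetic-data module generates LD-structured
    genotype panels, cis-heritable molecular traits, GWAS Z-scores under a
    mediation model, and gene-set collections with controlled enrichment,
    so the whole pipeline can be exercised and calibrated without external
    data. Cis heritability is estimated with a Haseman-Elston moment
    estimator, and cis-SNP weights are trained by cross-validated selection
    among marginal top-SNP, ridge (BLUP), elastic net, and spike-and-slab
    estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
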