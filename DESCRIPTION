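Package: microtraj
Title: Longitudinal Skin Microbiome Trajectories, Batch Correction and
    Resilience Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for longitudinal 16S amplicon sequence variant (ASV)
    analyses of the human skin microbiome under travel designs with ordered
    phases (e.g. polar expeditions). Provides a Dirichlet-multinomial
    synthetic-data generator emulating a two-host Antarctic expedition,
    strict tabular readers and writers, conditional indoor-constant
    imputation with interpolation and standard scaling of environmental
    covariates, prevalence/abundance feature filtering, empirical-Bayes
    location/scale batch correction with covariate adjustment on log10
    abundances, alpha diversity (observed features, Chao1, Shannon,
    Simpson), Bray-Curtis beta diversity with principal coordinates
    analysis and PERMANOVA, baseline-divergence trajectories with a
    per-phase community resilience index, and environment/lifestyle
    association statistics (Spearman, point-biserial, per-taxon screens
    with false-discovery-rate control).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    vegan,
    SummarizedExperiment,
    S4Vectors,
    BiocGenerics,
    jsonlite,
    yaml
Suggests:
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'microbiome-experiment.R'
    'abundance-prep.R'
    'tables-io.R'
    'resilience.R'
    'association.R'
    'combat.R'
    'diversity.R'
    'metadata-prep.R'
    'microtraj-package.R'
    'synthetic-data.R'
    'pipeline.R'
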