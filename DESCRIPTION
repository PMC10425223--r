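Package: dysbiome
Title: Case/Control Gut-Microbiome Dysbiosis Analysis with Synthetic Benchmarks
Version: 0.1.0
Authors@R: person("Maintainer", "Dysbiome", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for case/control shotgun-metagenomic
    cohort studies: compositional transforms (CLR, rank-based inverse-normal),
    prevalence filtering, covariate-adjusted differential abundance with
    Benjamini-Hochberg FDR, log-ratio dysbiosis and function-imbalance scores,
    alpha/beta diversity with PERMANOVA and principal-coordinates analysis,
    covariate-adjusted Spearman association scans with heterogeneity testing,
    and strain typing from gene-family presence/absence profiles (Jaccard
    distance, complete-linkage clustering, differential gene families, Pfam
    over-representation). Every stage is verifiable against a synthetic-data
    generator with known planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
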