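Package: myelomics
Title: Proteogenomic Analysis of Plasma-Cell Malignancies
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of the computational pipeline used in
    proteogenomic profiling of plasma-cell disorders (MGUS, multiple myeloma,
    plasma-cell leukemia): TMT ratio formation against a per-plex internal
    standard with median-MAD normalization, valid-value filtering and
    downshifted-normal imputation; empirical-Bayes moderated two-sample
    t-tests with Benjamini-Hochberg control and cis/trans annotation of hits
    against chromosomal alterations; RNA-protein-copy-number integration
    including a CNV buffering score; single-sample GSEA projection and NMF
    consensus clustering with cophenetic rank selection; a bootstrap-
    stabilized, AIC-optimal multi-protein Cox risk score with quartile
    stratification and external transfer; band-level copy-number calling from
    1-Mb bins; and nomination of therapeutic targets from CRISPR dependency
    and surface-proteome data. A synthetic multiomics cohort generator with
    ground truth supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
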