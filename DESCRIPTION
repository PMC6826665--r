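Package: ihcarea
Title: Area-Based Quantification of DAB Immunohistochemistry and
    Myoepithelial Cell Statistics for Mammary Carcinoma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify 3,3'-diaminobenzidine (DAB) immunostained
    tumor area from brightfield RGB images by optical-density color
    deconvolution and intensity thresholding; to compute area-based
    immunoreactive scores (IRS and H-score variants weighted by
    weak/moderate/strong positive-area percentages); to aggregate
    per-cell myoepithelial phenotype annotations (spindle-shaped,
    hypertrophic, and neoplastic myoepithelial cells) into per-tumor
    percentage summaries; and to run the accompanying cohort statistics
    (linear models with ANOVA model comparison, tie-corrected Spearman
    rank correlations, category contrasts). A synthetic-data module
    generates immunohistochemistry image tiles with pixel-exact ground
    truth and correlated tumor cohorts via a Gaussian copula, so the
    full pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
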