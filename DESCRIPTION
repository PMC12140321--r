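Package: glycoCRC
Title: Paired Tumor/Normal Intact N-Glycopeptide Analysis for Colorectal
    Cancer Glycoproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative intact N-glycopeptide (IGP) analysis of
    paired tumor and normal-adjacent-tissue cohorts: parsing of
    pGlyco-style glycan composition strings and a five-class glycoform
    taxonomy (sialylated, fucosylated, sialo-fucosylated, high-mannose,
    high-HexNAc); protein-normalized IGP quantification with detection
    filtering, per-sample minimum imputation and batch centering;
    tumor-versus-normal differential statistics (Levene-gated t-test,
    Wilcoxon, median fold change); a six-group glycosite-protein network
    classification with Cytoscape export; per-sample glycoform-median
    ratio scores screened exhaustively by Mann-Whitney AUC; glycoprotein
    biomarker selection with ridge-penalized logistic combination models;
    N-glycosylation sequon motif enrichment; and a synthetic paired-cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    car,
    pROC,
    withr
Config/testthat/edition: 3
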