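Package: rsapath
Title: Relative Solvent Accessibility as a Structural Predictor of Missense
    Variant Pathogenicity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes per-residue solvent accessible surface area (Shrake-Rupley)
    from protein structures and converts it to relative solvent accessibility
    (RSA) using theoretical maximum areas. Curates protein missense variants
    into population, cancer, and neurodevelopmental-disorder groups using
    recurrence and cross-database filters, joins per-residue RSA, and evaluates
    RSA as a pathogenicity feature via domain-stratified Kruskal-Wallis and
    pairwise Wilcoxon tests and ROC/AUC analysis. Includes quantification of
    phospho/total immunoblot reporter ratios with paired tests against
    wild-type, and synthetic-data generators (toy structures with analytically
    known burial, variant tables with controlled group separation, blot tables
    with known fold-changes) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
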