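Package: marginpin
Title: Auxin-PIN-CUC Patterning Models and Quantification for the Leaf Margin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic models of auxin transport and PIN polarity on a leaf
    margin cell grid, in which a static CUC boundary-gene pattern promotes PIN
    phosphorylation and thereby either switches the PIN polarization rule from
    up-the-gradient to with-the-flux (polarization modulation model, PMM) or
    raises PIN transport efficiency (efficiency modulation model, EMM).
    Includes steady-state integration, polarity-field and convergence-point
    analysis, noise-robustness ensembles, cell-resolution polarity and
    expression quantification for microscopy-style cell tables (polarity
    classification, reversal-position estimation, polarity frequency
    contingency analysis, point-biserial correlation, per-sample regression,
    region-of-interest selection), leaf-silhouette morphometrics (Normalized
    Difference Margin Complexity), and seeded synthetic-data generators with
    planted ground truth for validating every quantification stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
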