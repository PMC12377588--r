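Package: idrvep
Title: Region-Stratified Analysis of Missense Variants and Variant Effect
    Predictors in Intrinsically Disordered Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies protein residues as disordered, intermediate, or
    ordered from AlphaFold-style per-residue pLDDT confidence scores,
    stratifies missense variant sets (pathogenic, benign, putatively benign)
    by structural region, and evaluates variant effect predictors (VEPs)
    in a region-aware manner: coverage filtering, score orientation, AUROC,
    Youden-optimal global and region-specific decision thresholds,
    sensitivity/specificity, and Cohen's kappa agreement within and between
    VEP groups. Includes a synthetic-data generator with known ground truth
    so the full pipeline can be exercised and calibrated without external
    downloads.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
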