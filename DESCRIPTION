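Package: pniscreen
Title: Nerve-Tumor Proximity Screening for Perineural Invasion in
    Histopathology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for screening pancreatic ductal adenocarcinoma histology
    for perineural invasion (PNI). Nerve and tumor are segmented
    independently into per-class confidence maps, post-processed with a
    confidence threshold and a small-focus (10,000 pixel) filter, and
    candidate fields are ranked by nerve-tumor minimum distance and
    encirclement for pathologist confirmation. Includes a seeded synthetic
    H&E-like tile generator with planted PNI events, threshold-sweep
    segmentation metrics (intersection-over-union, detection rate,
    false-alarm rate), a simulated case-level review, and the study-level
    comparison statistics (pooled two-proportion z-test, rank-sum test).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
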