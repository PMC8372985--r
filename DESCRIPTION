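Package: coaptR
Title: Static Biomechanics of Middle-Deltoid Coaptation After Reverse
    Shoulder Arthroplasty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Implements a string-on-pulley static model of the middle
    deltoid wrapping a reverse-shoulder glenosphere. Fits the implant
    least-squares sphere (ILSS) to oriented point clouds with normal-vector
    filtering and iterative distance pruning, cuts anatomical plane slices
    through labeled volumes with a cubic resampling kernel, constructs the
    tangent-line geometry of the deltoid fibers on each slice, and computes
    the coaptation/elevation ratio (CER) and deltoid moment arm (DMA) under
    simulated glenosphere lateralization. Includes a parametric synthetic
    post-arthroplasty shoulder generator with closed-form ground truth,
    exact small-sample Mann-Whitney tests and intraclass correlation
    agreement statistics, and study-style report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    RNifti,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
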