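Package: ztread
Title: Quantifying Treadmilling Dynamics of Membrane-Bound FtsZ Rings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the treadmilling dynamics of ring-shaped
    cytoskeletal polymers (such as membrane-targeted FtsZ) imaged by TIRF
    microscopy on supported lipid bilayers. Builds circular kymographs
    around user-seeded rings and estimates rotation speed and chirality
    from the Fourier phase of the travelling intensity pattern, with
    spectral quality gates. Measures single-molecule residence times by
    spot detection, nearest-neighbour linking and a constrained
    double-exponential survival fit that separates unbinding from
    photobleaching. Includes seeded synthetic-movie generators with full
    ground truth for validation, and derived metrics such as treadmilling
    filament length and surface-density regime classification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
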