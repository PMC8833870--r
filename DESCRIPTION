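Package: zoldose
Title: Organ and Tumor Dosimetry for 177Lu-Labelled Bone-Seeking
    Radiopharmaceuticals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A MIRD-schema internal-dosimetry pipeline for
    177Lu-DOTA-zoledronate and similar bone-seeking therapeutic
    radiopharmaceuticals. Takes per-patient time-activity measurements
    (SPECT organ activities and venous blood concentrations), fits
    constrained sums of exponentials, integrates them analytically to
    cumulated activities and residence times, maps measurements onto
    MIRD source organs (blood-based red-marrow model, leg scaling,
    cortical/trabecular skeleton partition), computes normalized organ
    doses from a configurable S-value matrix and tumor doses from a
    sphere model, and derives treatment-planning quantities: maximum
    tolerated injected activity, dose-limiting organ, and therapeutic
    indices. Includes a synthetic-patient generator with closed-form
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
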