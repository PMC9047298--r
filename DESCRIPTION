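Package: squealr
Title: Objective Acoustic Assessment of Porcine Voice from Squeal Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for objective, rater-independent assessment of pig voice
    quality from squeal recordings. Extracts fourteen aperiodic acoustic
    parameters (spectral energy quantiles, peak frequency, spectral flatness
    and flux, duration, RMS intensity, harmonics-to-noise ratio, and optional
    cepstral peak prominence) under three windowing schemes (whole-signal,
    eleven partial Hamming windows, and overlapping consecutive frames),
    screens candidate squeals by duration, rater noise score and artifact
    rules, and tests pre- versus post-surgery parameter shifts per animal
    with one-sided Wilcoxon rank-sum tests under Benjamini-Yekutieli false
    discovery rate control. Includes a synthetic squeal simulator (harmonic
    stack with controllable high-frequency roll-off and noise) so the whole
    pipeline is testable without recordings.
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
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
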