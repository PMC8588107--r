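Package: semgtaste
Title: Quantitative Taste-Stimulus Intensity Recognition from Facial Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for regressing the intensity of primary
    taste stimuli (Sour, Sweet, Bitter, Salty, Umami) from six-channel facial
    surface electromyography. Provides quadratic-variation-reduction baseline
    removal via a tridiagonal solve, an adaptive spectral-interpolation notch
    for 50 Hz power-line harmonics, sliding-window sample augmentation, a
    330-dimensional band-power and spectral/time-moment feature set,
    epsilon-support-vector regression with radial-basis kernel under
    five-fold cross-validation, greedy channel-wise grouped forward feature
    selection with an inflection-point stopping rule, per-muscle spectral
    activity summaries, and multi-subject pooling analysis. Includes a
    seeded synthetic sEMG generator emulating the hedonic structure of
    facial responses to tastants, so the whole pipeline is testable without
    human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    e1071,
    stats,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
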