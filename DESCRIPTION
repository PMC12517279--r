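Package: audscreen
Title: Rule-Based Classification of Occupational Noise-Related Hearing
    Disorders from Pure-Tone Audiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies serial pure-tone audiograms from occupational
    hearing-conservation programmes into six diagnostic categories per ear
    and per worker: normal hearing, hearing loss, hearing impairment,
    permanent and temporary standard threshold shift (PSTS/TSTS), and
    noise-induced hearing loss (NIHL).  Provides the validation apparatus
    used to benchmark such rule engines against expert gold-standard labels
    (sensitivity, specificity, predictive values, Cohen's kappa with
    Landis-Koch interpretation, and a k-fold cross-validation harness
    reporting fold means and standard deviations), a seeded synthetic cohort
    generator with known ground truth, an independently coded brute-force
    oracle for property testing, and CSV readers/writers plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    caret
Config/testthat/edition: 3
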