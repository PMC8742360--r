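Package: usvwhistle
Title: Aeroacoustics and Motor Control of Rodent Ultrasonic Vocalizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how rodent ultrasonic vocalizations (USVs) are
    produced by intralaryngeal whistles. Implements the three candidate
    aeroacoustic mechanisms (wall impingement, alar edge tone, shallow cavity
    tone) as closed-form frequency/length models with mode identification; an
    entropy-based detector for fictive USVs in excised-larynx pressure-ramp
    recordings, with time-frequency ridge extraction of peak-frequency
    contours; an embodied motor-control model mapping respiratory and
    laryngeal muscle activations to whistle frequency and stability, with
    gesture inversion from frequency and subglottal-pressure traces; a
    ground-truthed synthetic-data generator for pressure ramps, multi-mode
    clips and call-type targets; and summary-statistics comparisons
    (pooled two-sample t tests, length shortfalls, frequency-flow slopes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
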