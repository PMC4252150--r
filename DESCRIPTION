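Package: swayrqa
Title: Postural Sway, Recurrence Quantification, and Vection Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing force-plate centre-of-pressure (CoP)
    recordings in studies of visually induced self-motion illusions
    (vection). Implements linear stabilometric measures (sway path length,
    95% confidence-ellipse sway area, Romberg and sway-area ratios),
    recurrence quantification analysis (RQA) of the anterior-posterior sway
    series via time-delay embedding, extraction of visually evoked postural
    responses (VEPRs) from blocked optic-flow sessions, throttle-based
    vection metrics (maximum and onset latency), a Pearson correlation and
    paired t-test inferential layer, and a fully seeded synthetic cohort
    generator so the complete pipeline can be exercised end to end without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
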