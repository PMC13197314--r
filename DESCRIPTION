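Package: strikekin
Title: Spatio-Temporal Strategy Analysis for Striking Gestures that
    Slide an Object to a Target
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how people parameterize a ballistic
    striking gesture that sends an object sliding along a surface toward a
    target distance. Provides frictional sliding physics on inclined
    surfaces (optimal launch speed, stopping distance, a 12-condition
    task-demand grid), a synthetic motion-capture generator with three
    spatio-temporal strategy archetypes, kinematic event detection and
    performance-variable extraction from raw 250 Hz trajectories (contact
    detection from normalized fingertip deceleration), per-participant
    correlation signatures with Fisher-Z transformation and K-means strategy
    classification (elbow and Calinski-Harabasz validation), slope scaling
    analysis with one-way ANOVA, Tukey HSD and effect sizes, chi-square
    contingency analysis, and a hierarchical multiple factor analysis with
    first-eigenvalue block weighting and full contribution accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
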