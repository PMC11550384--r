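Package: soccal
Title: Calcium-Imaging and Behavior Analysis for Second-Order Fear Conditioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for miniscope calcium-imaging and freezing
    behavior recorded during second-order fear conditioning (SOC) in mice:
    whole-trace dF/F and peri-event Z-score normalization, pre/post AUC
    responsive-neuron classification, K-means response-archetype clustering
    with silhouette-based model selection, longitudinal matching of neurons
    across sessions, within-state maximum pairwise correlation compared by
    Cohen's d, and freezing-based memory metrics (per-cue freezing percent,
    extinction curves, second-order memory-strength ratio). Includes a
    seeded generator of synthetic SOC experiments (GCaMP6m-like transients
    with planted response classes, cue/shock event schedules and two-state
    freeze/move behavior) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
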