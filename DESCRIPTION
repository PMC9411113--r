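Package: flyaim
Title: Quantifying Drosophila Locomotion and Abnormal Involuntary Movement Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying single-fly locomotion from video-tracking
    trajectories (per-frame displacement, instantaneous speed, yawing, and
    freezing fraction) and for computing a sliding-window abnormal involuntary
    movement (AIM) score that counts frames whose instantaneous speed deviates
    from the local mean speed beyond a log-ratio threshold. Includes a seeded
    behavioral-state trajectory simulator (walk, freeze, burst) with a dose
    parameter emulating levodopa-induced dyskinesia-like movement, plus cohort
    summaries, percent-change tables, and permutation-based dose-trend tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
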