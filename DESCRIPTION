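Package: pyloric
Title: Quantification of the Crustacean Pyloric Rhythm in Long-Term Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the pyloric rhythm of the crustacean
    stomatogastric ganglion from spike-time recordings spanning hours to days:
    interspike-interval burst segmentation for PD and LP units, per-cycle
    period/frequency/phase tables referenced to PD burst onset, detection of
    transient frequency bouts by a trailing-mean rule, long-duration summaries
    (binned medians, hourly box statistics, daily means, fastest-window search,
    silence detection, saline-exchange contrasts), and the comparison
    statistics used in this literature (Pearson correlation, paired and pooled
    t tests, Mood's median test, split-plot mixed ANOVA). A synthetic-data
    generator emulating multi-day two-unit pyloric recordings makes every
    stage testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
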