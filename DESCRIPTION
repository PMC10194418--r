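Package: repower
Title: Repolarization Power of hERG Currents from Temperature-Dilated AP-Clamp Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate the physiological-temperature "repolarization
    power" of hERG (KCNH2) potassium channels -- the time integral of the
    current evoked by an action-potential voltage clamp -- from recordings
    made at room temperature. Implements time-dilated AP-clamp protocols,
    the matching time/current correction of dilated recordings, selection of
    the optimal dilation factor against a reference temperature, and a
    Q10-temperature-scaled Hodgkin-Huxley-style hERG current simulator with
    variant presets (loss- and gain-of-function), cell-to-cell conductance
    variability and recording artifacts, for validating the analysis without
    instrument data. Includes group summaries and rank-based comparisons of
    repolarization-power distributions, plain-text trace interchange formats
    and a deterministic fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
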