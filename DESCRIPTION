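Package: wristgsd
Title: Gait Sequence Detection from Wrist-Worn Accelerometry
Version: 0.1.0
Authors@R:
    person("Mobility", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection of gait sequences in long free-living recordings from a
    wrist-worn triaxial accelerometer, together with the complete validation
    harness used to benchmark such detectors: a synthetic wrist-signal
    generator with exact ground truth, seven norm-based detection algorithms
    with default and wrist-optimized parameter banks, 0.1-second windowed
    classification metrics, gait-sequence duration and count errors, ICC(2,1)
    agreement, a weighted performance index, paired algorithm comparisons with
    Benjamini-Hochberg adjustment, and grid-search parameter tuning. Includes
    delimited-text readers and writers and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
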