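Package: imudecomp
Title: Decomposing the Error Sources of IMU-Based Body-Segment Orientation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Quantifies, separately, the three error sources of inertial
    measurement unit (IMU) based body-segment orientation estimation
    against an optoelectronic reference: the definition of the body
    frames, the soft tissue artefact, and the orientation filter.
    Includes quaternion utilities, a gradient-descent (Madgwick) MARG
    orientation filter, ISB anatomical-landmark and rigid-marker-cluster
    frame construction, functional sensor-body, hand-eye and static-trial
    calibrations, the nine-way frame comparison isolating each error
    source with RMSD aggregation across repetitions and subjects, and a
    ground-truthed synthetic motion/marker/IMU data generator emulating a
    nine-trial football movement protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
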