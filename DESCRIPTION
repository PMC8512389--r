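Package: baroque
Title: Hybrid Bee-Swarm and Deep Q-Network Feature Selection for
    Wearable-Sensor Activity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for human activity recognition from
    inertial (accelerometer/gyroscope) signals. Implements BAROQUE, a hybrid
    of bee swarm optimization (BSO) over binary feature masks with a
    multi-agent deep Q-network local search, alongside plain BSO, tabular
    Q-learning (QBSO-style), DQN-only search, and genetic-algorithm, binary
    particle-swarm and ant-colony comparators, all sharing one memoized
    classifier-based fitness. Also provides the supporting signal chain:
    mean imputation, median and zero-phase Butterworth filtering, sliding
    window segmentation, a time- and frequency-domain feature catalogue, and
    synthetic data generators with planted ground truth for end-to-end
    testing without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    class,
    e1071,
    foreign,
    grDevices,
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
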