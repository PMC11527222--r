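Package: clockscore
Title: Automated Ordinal Scoring of the Clock-Drawing Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for automated scoring of scanned clock-drawing test (CDT)
    pages on the six-point ordinal scale used in dementia screening. Provides
    morphological extraction of the clock drawing from a scanned page (ruled
    line removal, ink-component clustering, density/aspect-ratio selection), a
    rank-consistent ordinal classification head with a shared weight vector
    and per-rank biases, an asymmetric ordinal cross-entropy loss whose alpha
    parameter trades score over-estimation against under-estimation, a small
    trainable convolutional backbone with a two-phase transfer-learning
    schedule, the full ordinal and binary evaluation-metric suite (weighted
    kappa, Goodman-Kruskal gamma, off-by-one accuracies, likelihood ratios),
    and a seeded synthetic clock-drawing generator so the whole pipeline is
    testable without access to restricted survey images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Classification, Preprocessing, Visualization
RoxygenNote: 7.3.3
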