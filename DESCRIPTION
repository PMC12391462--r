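Package: placeseq
Title: Place-Cell Ensemble Sequence Analysis for Detour Navigation Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for hippocampal CA1 ensemble recordings from
    detour navigation tasks on a square track maze. Provides occupancy-normalized
    place maps and remapping statistics with cell-identity shuffles, offline
    burst-frame and ripple detection, memoryless Bayesian decoding of linear
    position with weighted-correlation and maximum-jump trajectory statistics,
    theta-cycle quadrant-ratio sequence scoring with spike-jitter controls,
    first-order Markov models linking sleep sequence motifs (preplay, tuplets)
    to run theta sequences, plastic/elastic remapping indices, Marchenko-Pastur
    cell-assembly detection, regression-based variance decomposition of
    post-detour tuning, and flickering alternate-context decoding. Includes a
    synthetic-session generator with known ground truth so every stage is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    zoo,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
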