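Package: naseq
Title: Neuronal Activation Sequence Analysis for Working-Memory Spike Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and decoding neuronal activation sequences
    (NAS) in simultaneously recorded spike trains from delayed-navigation
    working-memory tasks.  A session of spike events is converted to
    spike-density functions, per-trial vectors of peak firing times, and a
    trial-by-trial correlation matrix whose leading eigenvector projection
    embeds trials in a low-dimensional similarity space.  The package
    quantifies trial-to-trial timing consistency against shuffle nulls,
    detects time-boundary cells that parcel the trial into epochs, links
    sequence geometry to visuospatial movement trajectories through discrete
    Frechet distances, and compares sequence-based and persistent-rate codes
    with cross-validated decoders.  A synthetic-session generator with
    planted ground truth supports recovery and calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, e1071
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
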