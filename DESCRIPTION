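Package: axotraffic
Title: Quantification of Axonal Endolysosome Trafficking and Axon Initial
    Segment Structure
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for kymograph-based quantification of axonal organelle
    trafficking and for structural analysis of the axon initial segment (AIS).
    Builds calibrated kymographs from timelapse stacks along wide polyline
    ROIs, classifies particle tracks into runs, pauses and oscillation using
    five-frame cutoffs, and aggregates per-axon trafficking statistics
    (stationary fraction, pause durations, directional velocities and run
    distances, net displacement). AIS structure is quantified by
    autocorrelation of membrane periodic skeleton intensity profiles,
    detection of F-actin patches in super-resolution images, and AIS length
    estimation from marker intensity profiles. Includes a two-channel
    particle-intensity colocalization analysis, a nonparametric group
    comparison report layer (median with distribution-free confidence
    intervals, Mann-Whitney, Kruskal-Wallis with Dunn post hoc), and seeded
    synthetic-data generators for every input so the full pipeline is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    tiff,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, CellBiology, Neuroscience, ImageAnalysis
RoxygenNote: 7.3.3
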