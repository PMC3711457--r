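Package: grooveDNA
Title: DNA Minor Groove Geometry from Helical Parameters, Structures and
    Trajectories
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing and modelling the geometry of the DNA minor
    groove. Fits standard reference frames to bases in atomic structures,
    computes intra-base-pair and base-pair-step helical parameters
    (shear/stretch/stagger/buckle/propeller/opening and
    shift/slide/rise/tilt/roll/twist), rebuilds duplex coordinates from
    complete or partial parameter sets including mean-dinucleotide B-form
    models, measures minor and major groove widths by the
    closest-interstrand-phosphate convention, detects steric clashes of
    purine 2-amino (N2) groups in compressed models, and summarises
    groove-width distributions over multi-model trajectories (kernel-density
    modes, Gaussian fits, normality verdicts, profile correlations). Includes
    a synthetic-data generator producing duplexes and trajectories with known
    ground truth, covering canonical and modified bases (inosine,
    2-aminopurine).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: StructuralPrediction, Software
RoxygenNote: 7.3.3
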