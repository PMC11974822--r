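Package: nascentRates
Title: Kinetic Rates of Initiation, Pause Release and Premature
    Termination from Nascent Transcription Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates per-gene RNA polymerase II kinetic rate constants
    from strand-specific nascent run-on sequencing data (PRO-seq,
    GRO-seq) in two experimental conditions. A two-compartment
    steady-state model relates pause-region and gene-body polymerase
    densities to rates of initiation, pause release, premature
    termination and elongation. The package extracts pause sums and body
    means from per-base signal tracks, normalizes them with
    median-of-ratios size factors, calibrates signal units to absolute
    polymerase occupancy with a saturation fit to ranked pause sums,
    computes fold changes and bounds on rate changes between conditions,
    infers the genome-wide ratio of premature termination to pause
    release from initiation-inhibition experiments, reports absolute
    rates, polymerase spacing and paused-polymerase half-lives, and
    classifies perturbed transcription factors as initiation or
    pause-release regulators. A synthetic-data generator with known
    kinetic ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    minpack.lm,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    DESeq2,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
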