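Package: gevitools
Title: Simulation and Analysis of Genetically Encoded Voltage Indicator Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing fluorescence time series from genetically
    encoded voltage indicators (GEVIs) acquired by point-scanning two-photon
    microscopy. Implements fractional fluorescence change (dF/F), baseline
    noise and signal-to-noise metrics, additive and divisive photobleaching
    correction, mono- and bi-exponential kinetics fitting, the d-prime
    spike-detectability statistic with its spike-train extension and a
    log-likelihood ROC threshold simulation, stimulus-locked ROI response
    quantification, and conduction-velocity and amplitude-attenuation
    summaries for dendritic recordings. A forward model converts membrane
    voltage waveforms into dF/F via direction-dependent bi-exponential
    indicator kinetics and into Poisson photon-count recordings under a
    random-access scanning schedule, providing a fully synthetic benchmark
    generator for the analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
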