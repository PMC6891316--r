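Package: drivefatigue
Title: EEG Brain-Network and Oculomotor Analysis of Driving Fatigue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multichannel EEG studies of driving
    fatigue and fatigue-countermeasure interventions. Extracts theta, alpha
    and beta rhythms by orthogonal wavelet-packet decomposition, builds
    thresholded functional brain networks from theta-band channel
    correlations with a data-driven significance-sweep threshold selection,
    computes graph metrics (mean clustering coefficient, characteristic path
    length, global efficiency), the spectral fatigue ratio beta/(theta+alpha),
    and a lateral eye-movement detector based on a sliding-window slope
    statistic with an anticorrelation gate on the F3/F4 channel pair.
    Includes a synthetic-study generator emulating the two-condition,
    seven-stage driving design, stage-wise and between-condition t tests,
    and EDF/CSV recording input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    graphics,
    tools,
    utils
Suggests:
    igraph,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
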