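Package: waveclust
Title: Wavelet-Based Detection of Frequency-Coupled Taxa in Microbial Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects pairs of microbial taxa (OTUs) whose abundance time
    series are coupled at distinct temporal frequencies. Each series is
    decomposed with a multilevel discrete wavelet transform; per-level
    cosine similarities are converted into thresholded, period-weighted
    interaction scores; frequency-interacting pairs are clustered into
    communities with the Markov clustering algorithm (MCL). Includes a
    permutation null with Benjamini-Hochberg FDR control, a bloom-dynamics
    simulator with planted associations for validation against Pearson
    correlation, Toda-Yamamoto lag-augmented Granger causality for linking
    community profiles to environmental drivers, partition-comparison
    metrics (mutual information, adjusted mutual information), and
    Jensen-Shannon beta-diversity lag curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
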