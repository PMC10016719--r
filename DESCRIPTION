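Package: neurochar
Title: Electrophysiology and Complexity Characterization of Neuron and Ion-Channel Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for characterizing simulated neuron and
    ion-channel models. Builds current-clamp stimulus protocols (square, ramp,
    pink-noise, short-square triples), extracts a 42-property electrophysiology
    feature set from voltage traces (spike detection, rheobase search,
    inter-spike-interval statistics, accommodation, frequency-filter fits),
    estimates variable-timestep computational complexity from integration
    step-count tables, performs nested PCA + density-based + K-means clustering
    of cell models, scores ion-channel voltage-clamp responses under
    per-protocol probabilistic-PCA models and clusters them with Ward linkage
    and an adaptive tree cut, and integrates somatic conductance densities
    parsed from NeuroML-subset XML into normalized channel densities (NCD) with
    bootstrap summaries. Ships a synthetic-data generator with known ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
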