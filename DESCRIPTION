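Package: kvquant
Title: Quantification of Delayed-Rectifier Currents, Calcium Spikes, ROS and
    Channel Clustering in Hippocampal Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for hippocampal-neuron excitability studies built
    around the somatic delayed-rectifier (Kv2.1) conductance: P/N leak
    subtraction and steady-state I-V analysis of whole-cell voltage-clamp
    sweeps with Boltzmann activation-curve fitting; spontaneous calcium-spike
    detection in per-ROI fluorescence traces using a percent-of-baseline
    threshold; hydroethidine ROS accumulation quantified as area under the
    curve above the pre-stimulus trend; immunofluorescence cluster ("puncta")
    area quantification yielding a somatic clusterization index; and the group
    statistics used to compare strains and treatments. Seeded synthetic-data
    generators for all four modalities carry ground truth so every stage can
    be validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
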