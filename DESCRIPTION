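Package: orntools
Title: Receptor-Optimized Ligand Discovery and Olfactory Neuron Response Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Descriptor-based discovery of odorant receptor ligands and
    quantification of olfactory receptor neuron (ORN) response kinetics.
    Implements Sequential Forward Selection of informative molecular
    descriptor subsets, radial-basis-function support vector regression
    with repeated k-fold ROC/AUC cross-validation, physicochemical library
    filtering and ranked virtual screening, together with spike-train
    analysis of ORN termination kinetics (phasic peak, half-decay, tonic
    plateau, response duration, prolonged-activator classification and
    masking by pre-exposure) and seeded synthetic-data generators with
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    ChemmineR,
    e1071,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ChemmineOB,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
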