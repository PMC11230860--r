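Package: mpnnscreen
Title: Multi-Target Message-Passing Neural Network Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ligand-based virtual screening pipeline for drug repurposing
    against obsessive-compulsive disorder targets. Builds per-target binding
    likelihood models (serotonin transporter SERT, dopamine D2 receptor,
    NMDA glutamate receptor) from SMILES with a directed message-passing
    neural network encoder and a feed-forward head, combines them into an
    unweighted ensemble score, and evaluates the ensemble on a heavily
    imbalanced screening library by repeated balanced undersampling with a
    threshold sweep. Includes a synthetic active/decoy generator with known
    ground truth, Ki-based activity filtering, and the standard
    AUROC/AUPRC/confusion-matrix metric panel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
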