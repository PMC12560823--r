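Package: molfuse
Title: Multimodal Molecular Self-Supervised Pretraining with
    Non-Overlapping Substructure Perturbations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Self-supervised pretraining and fine-tuning for small-molecule
    property prediction from three coupled views of a molecule: the 1D SMILES
    token sequence, the 2D attributed molecular graph, and the 3D conformer.
    A frequency-based (byte-pair-encoding style) substructure vocabulary
    segments SMILES into fragments aligned to atom-index sets, which makes it
    possible to perturb disjoint substructures per modality (token masking,
    node-feature masking, coordinate noising). Modality-specific encoders
    (self-attention over tokens, graph isomorphism message passing, and
    directional distance/angle message passing) feed a shared fusion
    transformer; reconstruction decoders and modality-specific losses drive
    pretraining, and an attention-pooled head supports fine-tuning with
    per-substructure attention export. Includes a deterministic synthetic
    molecule generator, scaffold-based dataset splitting, and CSV/SDF readers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ChemmineR,
    ChemmineOB,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
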