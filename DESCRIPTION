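Package: marginmap
Title: Intraoperative Surgical Margin Assessment and Tumor Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for intraoperative margin assessment
    of surgical excision specimens, using Mohs micrographic surgery for basal
    cell carcinoma as the model system. Provides gross-specimen 3D point-cloud
    measurement with grossing and inking recommendations, whole-slide-image
    preprocessing (tissue masking, patch extraction, section and piece
    assignment, alpha-shape hole candidates), patch-graph tumor and tissue
    completeness prediction with a convolutional embedding backbone and graph
    attention networks, ink-based tissue orientation, follicle-confounder
    score docking, sliced-Wasserstein optimal-transport mapping of histological
    findings onto surgeon-drawn tumor maps, and concordance statistics
    (macro-AUC, cluster bootstrap, Jeffreys Beta posterior). Includes seeded
    synthetic fixture generators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    jsonlite,
    png,
    parallel,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
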