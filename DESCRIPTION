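Package: promptpose
Title: Animal Pose Estimation with Dynamic Conditional Language Prompts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A self-contained framework for top-down animal pose estimation by
    contrastive language-image training with dynamic conditional prompts.
    Keypoint text prompts are built from prefix/intermediate/suffix sentence
    templates and fused with learnable context vectors shifted by an
    image-conditioned token; prompt and keypoint-local image embeddings are
    matched contrastively, spatial similarity maps localize keypoints, and a
    heatmap head decodes coordinates. Includes COCO-format keypoint input and
    output for the 17-keypoint AP-10K and 20-keypoint Animal Pose schemas, a
    deterministic synthetic quadruped dataset generator, Object Keypoint
    Similarity (OKS) evaluation with the AP/AP50/AP75/APM/APL/AR metric
    family, small pure-R encoders trained with a built-in reverse-mode
    automatic-differentiation tape, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    yaml,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
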