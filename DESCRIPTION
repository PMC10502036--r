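Package: sranet
Title: Dual-Attention Polyp Segmentation Networks with Softmax-Gated Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implementation of SRaNet-style colonoscopy polyp segmentation:
    a shallow-attention operator that suppresses mucosal background using
    higher-level feature maps, a reverse-attention operator that emphasizes
    polyp boundaries via inverted normalized maps, and a per-channel softmax
    gate that adaptively fuses the two branches over a feature pyramid.
    Includes a compact reverse-mode differentiation engine so the full
    pipeline (Dice + binary cross-entropy training, saliency-style
    evaluation metrics, synthetic endoscopy-like data generation,
    augmentation with color exchange, and static MAC/parameter counting)
    runs on a CPU without external deep-learning frameworks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
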