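Package: lesionshift
Title: Label-Shift-Aware Self-Training for Cross-Tracer 3D Lesion Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised domain adaptation for anchor-based 3D lesion
    detection in dual-channel PET/CT volumes, aimed at the transfer from a
    labeled source tracer (FDG-like) to an unlabeled target tracer
    (PSMA-like) whose lesion count and size composition differ (label
    shift). Provides axis-aligned 3D box geometry (IoU, NMS, mask-to-box
    conversion), online target-domain priors over lesions-per-subject and a
    binned lesion-volume histogram with exponential-moving-average updates,
    quota-based pseudo-label selection by the largest-remainder method,
    epoch-wise anchor-shape adaptation via k-means and EMA, a compact
    CPU-scale anchor-based detector with focal and smooth-L1 losses, an
    alternating self-training loop, lesion-level AP and FROC evaluation,
    and a seeded synthetic dual-tracer volume simulator for end-to-end
    experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
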