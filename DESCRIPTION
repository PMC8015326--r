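Package: wormscore
Title: Detection Evaluation and Competitive Fitness Estimation for GFP-Marked Worm Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A detector-agnostic toolkit for estimating competitive fitness of
    Caenorhabditis elegans from two-class (GFP vs non-GFP) worm detections in
    fluorescence micrographs. Reads and writes Pascal VOC XML, COCO JSON,
    per-worm instance masks, and CSV detection/count tables; computes
    IoU-based detection matching, precision/recall and average precision and
    recall stratified by object size and animal density; assigns every
    detection and annotation to a five-way error taxonomy (correct,
    misclassified, counted twice, missed, false) and regresses error counts on
    animal density; and estimates focal-strain proportions per image and per
    pooled population together with method-bias regressions, paired Wilcoxon
    comparisons, and variability analyses. Includes a synthetic fluorescence
    scene generator (curved worm tubes, pharynx spots, clustering, edge-crossing
    animals, controlled detector error rates) and a deterministic classical
    reference detector, so the whole pipeline is testable without trained
    network weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
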