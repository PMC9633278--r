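Package: gwalign
Title: Feature-Based LC-MS Retention Time Alignment via Generalized
    Wasserstein Distance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns liquid chromatography-mass spectrometry (LC-MS) runs by
    matching detected features across chromatograms instead of warping the
    retention time axis. Each feature is treated as a discrete measure of
    signal peaks over the (retention time, m/z) plane and compared with an
    unbalanced (generalized) Wasserstein distance, computed either exactly as
    a minimum-cost flow or approximately by an entropically regularized
    Sinkhorn-Knopp scaling algorithm. Feature correspondence is resolved
    globally per chromatogram as a minimum-cost maximum-flow problem with an
    explicit trash option, after a centroid clustering stage proposes
    consensus candidates. Because matching is not constrained to be monotone
    in retention time, elution-order swaps are resolved correctly. Includes
    readers for OpenMS featureXML and a plain TSV dialect, alignment
    precision/recall/F-score and identification-recall evaluation, swap
    statistics, and a synthetic chromatogram and drift simulator with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    clue,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
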