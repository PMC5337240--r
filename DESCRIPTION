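Package: kytfroc
Title: Free-Response ROC Analysis for Hazard-Prediction (KYT) Observer Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing free-response observer studies of hazard
    prediction (Kiken-Yochi Training, KYT), in which observers mark suspected
    hazard locations in workplace scenes and attach a continuous confidence
    rating to each mark. Marks are scored as true or false positives against
    circular hazard-area ground truth, reduced to per-observer rating data,
    and summarised by empirical alternative free-response ROC (AFROC) curves
    and the Wilcoxon-type figure of merit, together with point- and
    event-based sensitivity, scene-based specificity, group summaries and
    paired/unpaired t tests on reader figures of merit. A synthetic-observer
    simulator generates scene sets and mark-rating responses with known skill
    parameters for validation and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
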