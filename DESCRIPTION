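Package: pqtlmr
Title: Proteome-Wide Two-Sample Mendelian Randomisation Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for proteome-wide two-sample Mendelian randomisation using
    GWAS summary statistics: harmonisation of exposure (pQTL) and outcome
    association tables with palindromic-variant exclusion and LD-proxy
    substitution, instrument selection with F-statistic and cis/trans
    classification, Wald ratio / inverse-variance weighted / MR-Egger /
    weighted-median / weighted-mode causal estimation, leave-one-out and
    Egger-intercept pleiotropy diagnostics, Steiger directionality testing,
    approximate-Bayes-factor colocalisation under the five-hypothesis
    decomposition, Benjamini-Hochberg multiple-testing control with tiered
    signal classification, and a summary-statistics simulator with known
    causal truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
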