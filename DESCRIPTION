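Package: medimr
Title: Two-Sample Mendelian Randomization Screening with Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) screens of many
    exposures against a single binary outcome from GWAS summary statistics:
    reading and harmonizing summary-statistic tables, instrument selection
    (p-value threshold, greedy LD clumping, F-statistic filtering), a
    five-estimator battery (inverse-variance weighted, MR-Egger, weighted
    median, simple and weighted mode), sensitivity diagnostics (Cochran's Q,
    Egger intercept, leave-one-out, a PRESSO-style outlier test), evidence
    tiering across estimators, reverse MR, and two-step mediation MR with
    bootstrap inference on the indirect effect. A seeded synthetic-GWAS
    generator with planted causal, pleiotropic and mediated effects supports
    end-to-end validation without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
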