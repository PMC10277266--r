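Package: phoskin
Title: Analytical Phosphate Kinetics for Single- and Multi-Pass Hemodialysis
Version: 0.1.0
Authors@R:
    person("phoskin", "developers", email = "phoskin@example.org", role = c("aut", "cre"))
Description: Compartmental models of phosphate kinetics during hemodialysis:
    exact analytical solutions of the single-pass (SP) model with and without
    ultrafiltration, a certified power-series solution of the multi-pass (MP)
    recirculating-dialysate model with Lagrange truncation-error bounds, the
    bi-exponential closed form for negligible ultrafiltration, post-dialysis
    rebound formulas, and a two-stage parameter-estimation pipeline
    (trapezoidal linear pre-estimate followed by bounded nonlinear least
    squares with Hessian-based confidence intervals) for SP, MP, and coupled
    (CP) data. Includes a synthetic-cohort generator emulating hourly
    blood/dialysate sampling and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
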