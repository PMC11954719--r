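Package: statinddi
Title: Pharmacokinetic Drug-Drug Interaction Analysis for Ritonavir-Boosted
    Statin Regimens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the pharmacokinetic interaction between a
    short low-dose ritonavir course (as used in nirmatrelvir/ritonavir
    therapy) and single-dose statins.  Provides noncompartmental exposure
    analysis (AUC, Cmax, terminal slope, clearance and volume measures,
    partial AUCs, molar activity sums), paired geometric-mean-ratio
    statistics with bioequivalence classification, a semi-mechanistic
    two-compartment model with zero-order absorption modulated by CYP3A
    enzyme turnover and mechanism-based inactivation, pooled and two-stage
    nonlinear regression for parameter recovery, multi-day dose-regimen
    simulation with exposure metrics, and a seeded virtual-trial generator
    emulating a paired baseline versus ritonavir-day-5 crossover design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
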