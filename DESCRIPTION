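Package: daptosim
Title: Daptomycin Exposure Simulation and Dose Adjustment in Renal Impairment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates daptomycin plasma exposure in adults and children with
    impaired renal function using a reduced linear disposition model whose
    clearance is decomposed into glomerular filtration (fup * GFR) and a
    constant non-renal (hepatic/biliary) route. Provides virtual-subject
    construction with renal staging, steady-state multi-dose infusion
    simulation with closed-form superposition, fold-error model validation
    against published observed/predicted tables, Monte-Carlo probability of
    target attainment and cumulative fraction of response for AUC/MIC
    pharmacodynamic targets, trough-concentration safety flagging, and the
    dose-adjustment logic for pediatric renal impairment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
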