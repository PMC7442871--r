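Package: vncua
Title: Individual Patient Sampling Cost-Utility Model for Ocular Gene Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lifetime cost-utility microsimulation comparing voretigene
    neparvovec (one-time subretinal gene-augmentation therapy for biallelic
    RPE65-mediated inherited retinal degeneration) against standard of care.
    Simulates individual patients through an annual-cycle two-state
    (alive/dead) Markov framework, tracking best-corrected visual acuity
    (logMAR) and Goldmann III4e visual field (sum total degrees) under
    natural history and treatment-effect scenarios, mapping visual function
    to utility, and accruing discounted direct and visual-impairment-banded
    indirect costs. Provides Monte Carlo ensembles, incremental QALY/cost
    summaries and cost-utility ratios, cost-effectiveness planes and
    acceptability curves, a deterministic sensitivity-analysis suite with
    common random numbers, utility calibration, and a synthetic
    Gompertz-Makeham life-table generator with a CSV interface for national
    period life tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
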