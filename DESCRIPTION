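Package: childmort
Title: Estimation and Scenario Projection of Under-5 and Neonatal Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating levels and trends in under-5 mortality
    (U5MR) and neonatal mortality (NMR) from multiple, possibly biased data
    sources, and for projecting child mortality to 2030 under policy
    scenarios. Implements a Bayesian B-spline bias-adjusted trend model for
    U5MR with a multiplicative, source-type-aware observation error model; a
    ratio model for NMR that guarantees NMR < U5MR; a birth-week cohort
    method converting rates and livebirths into annual death counts by age
    group; scenario projection with annual-rate-of-reduction logic, floors
    and ratio caps; and SDG 3.2 progress classification with regional
    aggregation. Includes a synthetic-world generator emulating the
    multi-source structure of national child-mortality databases so the full
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    rjags,
    coda,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
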