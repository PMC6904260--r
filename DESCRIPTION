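Package: medicaidcap
Title: Simulating Medicaid Block Grants and Per-Capita Caps for Health Centers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for projecting community health-center patient loads,
    revenues by payer, and staffing costs from state-by-year panels shaped
    like the Uniform Data System, and for simulating how converting federal
    Medicaid financing to an enhanced-match phase-out, a block grant, or a
    per-capita cap would change federal contributions, health-center
    revenues, and the nonclinical staffing cuts needed to preserve clinical
    capacity budget-neutrally. Includes a synthetic-data generator with
    known ground-truth parameters so the whole pipeline is testable without
    access to restricted source data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
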