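Package: crcscreen
Title: Resource Modelling for Colorectal Cancer Screening Programmes
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A Markov state-transition model of colorectal neoplasia for
    planning population-based screening programmes. Models the natural
    history of the adenoma-carcinoma sequence with age-specific transition
    probabilities obtained by calibration to cancer incidence (by stage)
    and mortality targets, superimposes screening by guaiac faecal occult
    blood test (gFOBT, with optional reflex FIT), faecal immunochemical
    test (FIT) or once-only flexible sigmoidoscopy (FSIG), and projects
    annual health-service resource use (test kits, diagnostic and
    surveillance colonoscopy, CT colonography, pathology, radiology,
    radiotherapy, colorectal resection), screening harms (bleeding,
    perforation, perforation death) and health outcomes over the first
    decade of a programme using a cross-sectional multi-cohort population
    approach. Includes one-way sensitivity analysis, comparison against a
    no-screening policy, staggered roll-out scenarios, and synthetic-data
    generators for population pyramids and calibration targets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
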