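# crcscreen

Resource modelling for population-based colorectal cancer (CRC)
screening programmes.

Cost-effectiveness results alone do not tell a health service how many
colonoscopies, pathology specimens or radiotherapy courses a screening
programme will actually demand next year, nor how many perforations and
deaths its endoscopy workload will cause. `crcscreen` answers those
planning questions: it projects, year by year over the first decade of
a programme, the expected resource use, harms and health outcomes of
screening an entire national population — for biennial guaiac faecal
occult blood testing (gFOBT, with optional reflex FIT), biennial faecal
immunochemical testing (FIT), or once-only flexible sigmoidoscopy
(FSIG) — and compares staggered roll-out strategies against screening
the full age range from the outset. It is written for health-economics
and screening-programme analysts.

## The model

The core is a discrete-time Markov state-transition model of the
colorectal adenoma–carcinoma sequence with annual cycles and 16 health
states: normal epithelium; low-risk (<10 mm) and intermediate/high-risk
(≥10 mm) adenomas; preclinical (screen-detectable) and clinical
(diagnosed) CRC, each staged I–IV; post-polypectomy states;
long-term cancer care; and death from CRC or other causes. For a cohort
with state-occupancy vector *x(t)* and age-banded transition matrix
*P(a)*,

&nbsp;&nbsp;&nbsp;&nbsp;*x(t+1) = x(t) P(a)*,

with annual adenoma onset *o(a) = o₀·exp(β(a−55))*, adenoma class
progression, sequential preclinical stage dwell, stage-specific clinical
presentation, and stage-specific case fatality competing with other-cause
(life-table) mortality. The unobservable transition probabilities
(15 parameters) are **calibrated** by weighted relative least squares
against age-band CRC incidence by stage and CRC mortality targets,

&nbsp;&nbsp;&nbsp;&nbsp;min Σᵢ wᵢ ((predᵢ − targetᵢ) / max(targetᵢ, ε))²,

minimised by bounded Levenberg–Marquardt with a seeded multistart.

Screening is superimposed on the natural history as expectation
arithmetic: invitation of the alive, never-diagnosed population in the
eligible ages; test completion at the modality's uptake; referral of
positives (class-specific sensitivity for lesion-bearing mass, 1 −
specificity for lesion-free mass); diagnostic colonoscopy at 86%
compliance, with CT colonography for those unfit; polypectomy and
surveillance entry for detected adenomas; and stage-specific management
of detected cancers. The whole-population projection runs 70 single-year
age cohorts (ages 30–99) through 10 calendar years and sums every
ledger field per year — the cross-sectional approach of a budget-impact
analysis rather than the lifetime single-cohort approach of a
cost-effectiveness analysis.

Because no registry calibration targets or census microdata ship with
the package, a synthetic-data module generates the study conditions:
a population pyramid with a configurable total and 55–74 share, and
calibration targets computed from known parameters (enabling
parameter-recovery testing of the calibration machinery end to end).

## Worked example

```r
library(crcscreen)

toy <- toy_ireland()     # synthetic population + calibrated model + test profiles
led <- run_scenario(toy$pyramid, toy$model, scenario_spec("FIT"), toy$config)
rep <- report_ledger(led)
rep[rep$field %in% c("kits_sent", "kits_processed", "diagnostic_col",
                     "surveillance_col", "adenoma_persons_total",
                     "crc_total", "perforations"),
    c("field", "year_1", "year_5", "year_10")]
```

```
                 field year_1 year_5 year_10
             kits_sent 352144 358310  376763
        kits_processed 186636 189904  199684
        diagnostic_col  11453  11184   11508
      surveillance_col      0   1604    3213
 adenoma_persons_total   4666   4305    4259
             crc_total    521    400     377
          perforations     17     18      20
```

Reading the table: in year one roughly 352,000 invitations yield
187,000 returned FIT kits (53% uptake), requiring about 11,500
diagnostic colonoscopies; surveillance colonoscopy demand is zero in
year one (nobody yet has screen-detected adenomas) and builds to ~3,200
by year ten; detected-cancer yield falls across rounds as prevalent
disease is cleared from the screened pool; and the colonoscopy workload
carries an expected ~17–20 bowel perforations per year.

Comparing against a no-screening policy:

```r
rel <- relative_vs_no_screening(toy$pyramid, toy$model,
                                scenario_spec("FIT"), toy$config)
round(rel$comparison[c(1, 2, 5, 10), c("year", "cases_averted", "deaths_averted")])
```

```
 year cases_averted deaths_averted
    1          -396              0
    2          -277              3
    5            46             91
   10           250            211
```

Screening initially *increases* diagnosed cases (it brings diagnoses
forward), with the case count dropping below the no-screening policy
after about five years; CRC deaths averted are positive from year two
and grow throughout the decade.

A command-line wrapper (`inst/scripts/crcscreen`) exposes the same
pipeline as `calibrate` / `run` / `sensitivity` / `compare` subcommands
driven by a YAML run configuration; see `?crcscreen_main`.

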