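---
title: "Resource modelling for colorectal cancer screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resource modelling for colorectal cancer screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcscreen)
```

This vignette is the package's account of its model: the structure and
assumptions, the parameters that matter, the numerical conventions, the
design choices that were genuinely open, and the limits of what the
synthetic test fixture can demonstrate.

## The natural-history model

Colorectal cancer develops overwhelmingly through the
adenoma–carcinoma sequence: normal epithelium gives rise to
adenomatous polyps, a minority of which grow, acquire advanced
histology, and transform into invasive carcinoma, which progresses
through stages I–IV and eventually surfaces clinically through
symptoms. Screening interrupts the sequence twice: by removing
adenomas before transformation (incidence reduction, delayed) and by
detecting preclinical cancer at an earlier stage than symptomatic
presentation (mortality reduction, faster).

The model is a discrete-time Markov chain with annual cycles over 16
states (`health_states()`): `Normal`; `AdenomaLowRisk` (<10 mm) and
`AdenomaIntHighRisk` (≥10 mm); `PreclinicalCRC_I`–`IV`;
`ClinicalCRC_I`–`IV`; two post-polypectomy states
(`SurveillanceLowRisk`, `SurveillanceIntHighRisk`); `CancerCare`
(long-term survivors); and the absorbing `CRCDeath` and `OtherDeath`.
Stage progression in the preclinical compartment is sequential
(I→II→III→IV); the stage mix at clinical presentation is not imposed
but emerges from the competition between stage dwell and stage-specific
presentation rates. No half-cycle correction is applied: outputs are
annual event counts for service planning, not discounted person-time.

Transition matrices are age-banded (5-year bands from 30 to 100 by
default, configurable through `age_breaks`), with rates evaluated at
band midpoints. Other-cause mortality is a life-table-style input — a
per-year-of-age probability vector, by default a Gompertz schedule
(`gompertz_mortality()`) — and competes proportionally with every
disease transition. CRC case fatality is deliberately *not* discounted
by the competing other-cause risk, since it measures death from the
cancer itself. Cohorts exit the model at age 100, with remaining alive
mass absorbed into other-cause death.

### Parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| `onset_base` | adenoma onset at age 55 | 1/yr | 0.008 |
| `onset_slope` | log-linear age trend of onset | 1/yr of age | 0.04 |
| `low_to_inthigh` | low-risk → int/high-risk adenoma | 1/yr | 0.035 |
| `inthigh_to_crc` | int/high-risk adenoma → preclinical CRC I | 1/yr | 0.03 |
| `progression` | preclinical stage dwell exits I→II, II→III, III→IV | 1/yr | 0.40, 0.45, 0.48 |
| `presentation` | clinical presentation from preclinical I–IV | 1/yr | 0.10, 0.28, 0.50, 0.90 |
| `fatality` | CRC death from clinical I–IV | 1/yr | 0.01, 0.04, 0.15, 0.45 |
| `remission` | clinical I–IV → long-term cancer care | 1/yr | 0.20, 0.15, 0.08, 0.02 |

The first fifteen (all but `remission` and the other-cause schedule)
are the calibrated quantities. The defaults were chosen once so that
the resulting synthetic epidemiology is realistic for a western
European population of the late 2000s: crude CRC incidence of roughly
115 per 100,000 in the 30+ population, a stage split at presentation of
roughly 22/31/24/22% across stages I–IV, and a mortality-to-incidence
ratio of about 0.4. They are a *reference truth* for the synthetic
fixture, not estimates for any real population.

## Calibration

Transition probabilities of preclinical disease cannot be observed
directly; they are estimated by fitting the model's cross-sectional
age-specific rates to targets: CRC incidence by stage and CRC
mortality, per 100,000 alive, by age band. Predicted rates come from a
single sweep of a unit cohort from age 30 to 99 (`predicted_rates()`),
so one objective evaluation costs one 70-step matrix recursion.

The objective is weighted relative least squares,
$\sum_i w_i ((p_i - t_i)/\max(t_i, \varepsilon))^2$ with
$\varepsilon = 0.1$ per 100,000 guarding near-zero targets. Relative
errors put incidence and mortality — and young and old bands, whose
rates differ by two orders of magnitude — on comparable scales.

Minimisation uses bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) on
the residual vector, wrapped in a seeded multistart (first start at
`init`, further starts log-normal perturbations of it; 3 starts by
default). LM with a numerical Jacobian is the natural optimiser for a
smooth least-squares objective of this size and reaches the generating
parameters of noise-free synthetic targets to near machine precision;
a derivative-free simplex search was rejected as both slower and less
reliable in 15 dimensions. Parameter points at which competing exits
from a state would sum above one (an infeasible chain) receive a large
penalty residual graded by the violation, and all starts are projected
into the feasible region first.

Two identifiability conventions:

* The two sequential adenoma-compartment rates (`low_to_inthigh`,
  `inthigh_to_crc`) enter the incidence predictions symmetrically —
  two-stage transit-time distributions are invariant under exchange of
  their rates — so the fit reports the labelling with
  `low_to_inthigh ≥ inthigh_to_crc`, applied post-hoc via the exact
  exchange symmetry (the objective is re-evaluated and the swap kept
  only if it does not worsen the fit, which guards against the
  symmetry being broken by strongly age-varying attrition).
* Stage-specific fatality is identified from the single mortality
  curve because the four clinical-stage prevalences have linearly
  independent age profiles; the default 5-year bands give 70 targets
  for 15 parameters.

`calibrate_transitions()` is deterministic given its seed, returns the
best local minimiser with its objective, evaluation count and a
convergence flag, and — if the evaluation budget is exhausted — the
best-so-far parameters with a warning rather than an error.

## The screening overlay

A screening round is expectation arithmetic on the cohort's state
distribution (`screen_round()`): invitation of alive, never-diagnosed
mass; completion at uptake; per-state positivity (class sensitivity for
lesion states, 1 − specificity for lesion-free); work-up at colonoscopy
compliance, split to CT colonography by the unfit fraction; detection
at the work-up test's class sensitivity. Detected low-risk adenoma
persons move to `SurveillanceLowRisk` (no scheduled follow-up but no
longer invitable — any adenoma diagnosis ends screening eligibility);
intermediate/high-risk persons enter the surveillance schedule.
Missed lesions, non-compliant positives (14%) and false positives
return to their underlying state; false-positive work-ups still count
colonoscopies and harms. The gFOBT pathway supports a reflex FIT stage
(`reflex_gfobt_round()`): a configurable fraction of gFOBT positives is
weak and re-tested, and only strong positives plus FIT-confirmed weak
positives are referred. With the default `weak_positive_fraction = 0`
the published single gFOBT profile is interpreted as the operating
characteristics of the complete gFOBT-plus-reflex algorithm, and the
reflex machinery is available for scenario exploration.

Flexible sigmoidoscopy reaches the distal colon only: its sensitivities
apply to the `distal_fraction` (default 0.60) of neoplasia, and every
FSIG examination itself incurs FSIG harm rates. Colonoscopy harms
distinguish procedures with polypectomy (adenoma found) from those
without.

### Timing within a calendar year

Each projection year runs: surveillance exams falling due → the
screening round → one natural-history cycle. Two consequences are
deliberate:

* A surveillance interval of *k* years means the exam happens exactly
  *k* annual shifts after scheduling.
* Screen-detected cancers are removed from the preclinical compartment
  at detection but enter the clinical states only at the end of the
  year's cycle (the `pending_clinical` slot merged by `step_cohort()`).
  Newly diagnosed cases by either route — screen detection or clinical
  presentation during the cycle — therefore face CRC death risk from
  the following year. Without this convention the annual
  discretisation would force every screen-detected case to begin dying
  a full year before its counterfactual presentation, biasing the
  relative analysis against screening in early years.

### Management of screen-detected cancer

A stage-specific fraction of screen-detected cancers
(`screen_detect_cure()`, defaults 0.95/0.80/0.60/0.20 for stages
I–IV) is cured by resection at diagnosis and moves directly to
`CancerCare`; the remainder follows the clinical-state
fatality/remission dynamics of symptomatically presenting disease.
Screen-detected cancer has better stage-specific survival than
symptomatic cancer — it is caught earlier within stage and avoids
emergency presentation — and the defaults track stage-specific
survival of screen-detected disease. This is the mechanism through
which the relative analysis shows deaths averted from the second
programme year, with the incidence benefit of polypectomy following
years later.

### Surveillance

Intermediate-risk detections are recalled at 3 years, the 29% of
int/high-risk detections that are high-risk at 1 year, then all
three-yearly — a committed reading of standard post-polypectomy
guidelines, consistent with surveillance colonoscopy demand being zero
in programme year one. Attendance uses the diagnostic compliance
(86%); non-attenders are recalled the next year. Each exam finds new
intermediate/high-risk adenomas with probability `inthigh_yield`
(default 0.06, in the range reported for first surveillance exams);
finders restart the schedule. Persons under surveillance remain in
their surveillance state — their adenomas were removed, and new
neoplasia within the 10-year horizon is represented only through the
surveillance findings themselves, not through re-entry into the
natural-history adenoma states. This understates the (small)
contribution of post-polypectomy patients to late-decade incidence.

## The population projection

`run_scenario()` runs 70 single-year age cohorts through the
10-year horizon. Cohorts are initialised at their baseline age by
burn-in from age 30 (all normal epithelium), conditioned on being
alive, so the baseline population carries realistic prevalences of
adenomas, preclinical disease and prior diagnoses. There is no
in-migration and no new age-30 entry during the horizon: within ten
years neither can reach the screening ages, so demographic change
arises solely from cohort ageing and mortality.

Invitation schedules (`invited_ages()`): biennial screening invites the
ages at an even offset from the lower age bound every year — a
deterministic rendering of "half of each two-year band each year" —
so each individual is re-invited every second year as they age through
the range. The medium roll-out anchors two-year bands at ages 55 and
65 and adds one band per anchor per year (full range in year five);
the slow roll-out anchors at 55 only (full range in year ten); the
invited sets nest (slow ⊆ medium ⊆ base) by construction. FSIG invites
exactly the screening age (60), so each person is invited once on
reaching it.

CRC work-up resources (CT, MRI, PET, transrectal ultrasound,
pre-operative radiotherapy, resection) are fixed fractions of detected
cancers (`crc_workup_fractions()`; CT staging applies to all). The
defaults are reverse-derived from the year-one ratios of a published
resource table for the gFOBT scenario, since the fractions themselves
are not printed anywhere; they are configuration, not estimates. The
fraction of work-ups done by CT colonography (0.115) is likewise
derived from the printed year-one FIT ratio of CT colonographies to
colonoscopies.

All internal accumulators are fractional expectations; rounding (half
away from zero) happens only in `report_ledger()`, where the pathology
row is recomputed from the rounded detection counts so the printed
identity `pathology = round(1.9 × adenoma persons) + CRC` holds
exactly.

## Analyses

`one_way_sensitivity()` re-runs the full projection with one parameter
of the scenario's test at its low/base/high values (sensitivity values
vary the class sensitivities jointly). Year-one resource and detection
counts are exactly linear in uptake — nobody invited in year one has
any screening history — so year-one percentage changes under uptake
variation are fixture-independent ratios of the uptake values.
Percentage changes are reported rounded to the nearest integer percent.
On specificity, the package follows the mechanics: higher specificity
means fewer false positives and therefore *fewer* diagnostic
colonoscopies, with the work-up change equal to the false-positive
change on the lesion-free screened mass.

`relative_vs_no_screening()` differences two runs on identical inputs.
Cases averted are negative in early years (diagnoses brought forward)
before turning positive as polypectomy suppresses incidence; deaths
averted emerge from the stage shift and the screen-detection survival
advantage.

## The synthetic fixture: what it does and does not show

`toy_ireland()` assembles the canonical test instance: a population of
4.4 million with 700,800 aged 55–74 (the pyramid holds the ages-30–99
portion, 58% of the total, with a log-linear "bulge" slope of 0.026
per year of age matching the ~1.3:1 ratio of the 45–54 to the 55–64
age groups in a demographically young western population), the default
natural-history parameters as calibrated truth, and the published
base-case test profiles. Generators are pure functions of their
arguments; pyramids meet their totals exactly by largest-remainder
rounding applied separately inside and outside the 55–74 block.

Passing tests on this fixture demonstrate the *machinery*: that
calibration recovers known parameters from targets the model itself
generated (by construction a zero-residual problem), that the
projection conserves mass and respects the scheduling and eligibility
rules, that screening arithmetic matches hand-computed expectations,
and that cohort expectations agree with an independent individual-level
microsimulation of the same chain. They do not validate the defaults
against any real registry: real calibration targets are noisy,
real test performance drifts across rounds, FIT performance depends on
the analytic cut-off, and real populations migrate. Absolute projected
magnitudes on the fixture are therefore illustrative; the published
arithmetic identities and the year-one proportionality results are the
quantities that transfer.

## Numerical conventions and degenerate inputs

* Row-stochasticity is enforced to 1e-12 at build time; validation
  errors name the offending state and age band. Mass conservation is
  tested to 1e-9 over a 70-cycle lifetime.
* Cohort distributions must sum to 1 within 1e-9 at construction.
* A cohort at age ≥ 100 exits the model (absorbed, not an error); an
  empty pyramid is an error; an uncalibrated sentinel model is refused
  by `run_scenario()` with an instruction to calibrate first.
* `round_half_out()` (half away from zero) is the single reporting
  rounding convention.
* Calibration problem size in the tests: 70 targets, 15 parameters,
  ~400 residual evaluations per recovery, run once in the unit suite
  and once in the acceptance suite. The microsimulation oracle uses
  1e5 individuals over 40 years, the scale at which three binomial
  standard errors resolve occupancy differences of ~0.4%.

## Known limitations

* Anatomical site (distal/proximal) is a fixed fraction at FSIG
  screening, not a state dimension; site-specific dwell differences
  are out of scope.
* Test sensitivity and specificity are constant across rounds.
* Surveillance-state persons do not re-enter the natural-history
  adenoma compartments (see above).
* Harms are expectations from fixed per-procedure rates; no
  case-mix or endoscopist-volume effects.
* No costing, discounting, QALYs, or horizons beyond ten years.
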