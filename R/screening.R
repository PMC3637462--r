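#' Screening test profile
#'
#' Operating characteristics and uptake of one screening modality.
#' Sensitivity is class-specific (low-risk adenoma, intermediate/high-risk
#' adenoma, CRC); a single specificity applies to lesion-free colons.
#' Flexible sigmoidoscopy examines the distal colon only
#' (`reach = "distal_only"`); its sensitivities apply to distal lesions
#' and are scaled by the distal fraction at screening time.
#'
#' @param name One of `"gFOBT"`, `"FIT"`, `"FSIG"`.
#' @param sens_low_adenoma,sens_inthigh_adenoma,sens_crc Sensitivities by
#'   lesion class.
#' @param specificity Probability a lesion-free person tests negative.
#' @param reach `"whole_colon"` or `"distal_only"`.
#' @param uptake Probability an invited person completes the test.
#' @return Object of class `test_profile`.
#' @export
test_profile <- function(name, sens_low_adenoma, sens_inthigh_adenoma,
                         sens_crc, specificity,
                         reach = c("whole_colon", "distal_only"),
                         uptake) {
  reach <- match.arg(reach)
  p <- c(sens_low_adenoma, sens_inthigh_adenoma, sens_crc, specificity,
         uptake)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("all test-profile probabilities must lie in [0, 1]")
  if (!(sens_crc >= sens_inthigh_adenoma &&
        sens_inthigh_adenoma >= sens_low_adenoma))
    stop("expected sens_crc >= sens_inthigh_adenoma >= sens_low_adenoma")
  structure(list(name = name, sens_low_adenoma = sens_low_adenoma,
                 sens_inthigh_adenoma = sens_inthigh_adenoma,
                 sens_crc = sens_crc, specificity = specificity,
                 reach = reach, uptake = uptake),
            class = "test_profile")
}

#' Diagnostic work-up pathway
#'
#' Positive screening tests are investigated by colonoscopy or, in the
#' fraction unfit for colonoscopy, by CT colonography (CTC).
#'
#' @param colonoscopy_compliance Probability a screen-positive person
#'   attends diagnostic work-up.
#' @param ctc_fraction_of_workups Fraction of attended work-ups done by
#'   CTC instead of colonoscopy.
#' @param col_sens_low,col_sens_inthigh,col_sens_crc,col_spec Colonoscopy
#'   operating characteristics by lesion class.
#' @param ctc_sens_low,ctc_sens_inthigh,ctc_sens_crc,ctc_spec CT
#'   colonography operating characteristics.
#' @return Object of class `diagnostic_pathway`.
#' @export
diagnostic_pathway <- function(colonoscopy_compliance = 0.86,
                               ctc_fraction_of_workups = 0.115,
                               col_sens_low = 0.77, col_sens_inthigh = 0.98,
                               col_sens_crc = 0.98, col_spec = 0.97,
                               ctc_sens_low = 0.53, ctc_sens_inthigh = 0.85,
                               ctc_sens_crc = 0.85, ctc_spec = 0.86) {
  p <- c(colonoscopy_compliance, ctc_fraction_of_workups, col_sens_low,
         col_sens_inthigh, col_sens_crc, col_spec, ctc_sens_low,
         ctc_sens_inthigh, ctc_sens_crc, ctc_spec)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("all diagnostic-pathway probabilities must lie in [0, 1]")
  structure(list(colonoscopy_compliance = colonoscopy_compliance,
                 ctc_fraction_of_workups = ctc_fraction_of_workups,
                 col_sens_low = col_sens_low,
                 col_sens_inthigh = col_sens_inthigh,
                 col_sens_crc = col_sens_crc, col_spec = col_spec,
                 ctc_sens_low = ctc_sens_low,
                 ctc_sens_inthigh = ctc_sens_inthigh,
                 ctc_sens_crc = ctc_sens_crc, ctc_spec = ctc_spec),
            class = "diagnostic_pathway")
}

#' Endoscopy harm rates
#'
#' Per-examination probabilities of major bleeding, bowel perforation and
#' death following perforation, for flexible sigmoidoscopy and for
#' colonoscopy with and without polypectomy.
#'
#' @param fsig_perf,fsig_perf_death,fsig_bleed FSIG harm probabilities.
#' @param col_perf_polyp Perforation probability, colonoscopy with
#'   polypectomy.
#' @param col_perf_nopolyp Perforation probability, colonoscopy without
#'   polypectomy.
#' @param col_perf_death Death probability after colonoscopy perforation.
#' @param col_bleed Major-bleeding probability per colonoscopy.
#' @return Object of class `harm_rates`.
#' @export
harm_rates <- function(fsig_perf = 0.00002, fsig_perf_death = 0.06452,
                       fsig_bleed = 0.00029, col_perf_polyp = 0.00216,
                       col_perf_nopolyp = 0.00107, col_perf_death = 0.05195,
                       col_bleed = 0.00379) {
  p <- c(fsig_perf, fsig_perf_death, fsig_bleed, col_perf_polyp,
         col_perf_nopolyp, col_perf_death, col_bleed)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("all harm rates must lie in [0, 1]")
  structure(list(fsig_perf = fsig_perf, fsig_perf_death = fsig_perf_death,
                 fsig_bleed = fsig_bleed, col_perf_polyp = col_perf_polyp,
                 col_perf_nopolyp = col_perf_nopolyp,
                 col_perf_death = col_perf_death, col_bleed = col_bleed),
            class = "harm_rates")
}

#' Post-polypectomy surveillance rule
#'
#' Persons with intermediate/high-risk adenomas removed enter a
#' surveillance colonoscopy schedule: first examination after
#' `interval_years_intermediate` years (intermediate risk) or
#' `interval_years_high` years (the `high_risk_fraction` whose adenoma
#' was high-risk), then three-yearly.  `inthigh_yield` is the probability
#' a surveillance examination finds new intermediate/high-risk adenomas
#' (such persons restart the schedule).
#'
#' @param interval_years_intermediate,interval_years_high First-exam
#'   intervals in years (>= 1).
#' @param high_risk_fraction Fraction of intermediate/high-risk adenoma
#'   detections that are high-risk.
#' @param inthigh_yield Per-exam probability of finding new
#'   intermediate/high-risk adenomas.
#' @param applies_to Detection class under surveillance (fixed).
#' @return Object of class `surveillance_rule`.
#' @export
surveillance_rule <- function(interval_years_intermediate = 3,
                              interval_years_high = 1,
                              high_risk_fraction = 0.29,
                              inthigh_yield = 0.06,
                              applies_to = "AdenomaIntHighRisk") {
  if (interval_years_intermediate < 1 || interval_years_high < 1)
    stop("surveillance intervals must be at least 1 year")
  if (high_risk_fraction < 0 || high_risk_fraction > 1 ||
      inthigh_yield < 0 || inthigh_yield > 1)
    stop("fractions must lie in [0, 1]")
  structure(list(interval_years_intermediate =
                   as.integer(interval_years_intermediate),
                 interval_years_high = as.integer(interval_years_high),
                 high_risk_fraction = high_risk_fraction,
                 inthigh_yield = inthigh_yield,
                 applies_to = applies_to),
            class = "surveillance_rule")
}

#' Surgical cure fractions for screen-detected CRC
#'
#' Stage-specific probability that a screen-detected cancer is cured by
#' resection at diagnosis (moving directly to long-term cancer care with
#' negligible CRC death risk).  Screen-detected cancers have better
#' stage-specific survival than symptomatic presentations (detected
#' earlier within stage, fewer emergency presentations); symptomatic
#' cases instead follow the clinical-state case-fatality/remission
#' dynamics.  Defaults track stage-specific survival of screen-detected
#' disease.
#'
#' @param I,II,III,IV Cure probabilities by stage.
#' @return Named numeric vector of length 4.
#' @export
screen_detect_cure <- function(I = 0.95, II = 0.80, III = 0.60, IV = 0.20) {
  v <- c(I = I, II = II, III = III, IV = IV)
  if (any(v < 0) || any(v > 1)) stop("cure fractions must lie in [0, 1]")
  v
}

#' Expected endoscopy harms
#'
#' @param n_col_polyp Colonoscopies with polypectomy.
#' @param n_col_nopolyp Colonoscopies without polypectomy.
#' @param n_fsig Flexible sigmoidoscopies.
#' @param harms A [harm_rates()] object.
#' @return Named numeric vector: expected `bleeds`, `perforations` and
#'   `perf_deaths` (fractional expectations; rounding happens only in
#'   final reports).
#' @examples
#' expected_harms(0, 10000, 0, harm_rates())  # 10.7 perforations
#' @export
expected_harms <- function(n_col_polyp, n_col_nopolyp, n_fsig, harms) {
  stopifnot(n_col_polyp >= 0, n_col_nopolyp >= 0, n_fsig >= 0)
  perf_col <- n_col_polyp * harms$col_perf_polyp +
    n_col_nopolyp * harms$col_perf_nopolyp
  perf_fsig <- n_fsig * harms$fsig_perf
  c(bleeds = (n_col_polyp + n_col_nopolyp) * harms$col_bleed +
      n_fsig * harms$fsig_bleed,
    perforations = perf_col + perf_fsig,
    perf_deaths = perf_col * harms$col_perf_death +
      perf_fsig * harms$fsig_perf_death)
}

# Per-state screening positivity for a test profile.  Lesion-bearing
# states test positive with the class sensitivity (scaled by the distal
# fraction for a distal-only test); lesion-free invitable mass tests
# positive with 1 - specificity.
screening_positivity <- function(test, distal_fraction) {
  reach <- if (test$reach == "distal_only") distal_fraction else 1
  pos <- stats::setNames(numeric(16L), health_states())
  pos["Normal"] <- 1 - test$specificity
  pos["AdenomaLowRisk"] <- reach * test$sens_low_adenoma
  pos["AdenomaIntHighRisk"] <- reach * test$sens_inthigh_adenoma
  pos[.preclin] <- reach * test$sens_crc
  pos
}

# Core expectation arithmetic shared by screen_round() and
# reflex_gfobt_round().  `positivity` is the per-state probability that a
# screened person tests positive (and is referred for work-up).
screen_core <- function(state, uptake, positivity, pathway, harms, rule,
                        fsig_exam = FALSE, test_name = "test",
                        detect_cure = screen_detect_cure()) {
  stopifnot(inherits(state, "cohort_state"),
            inherits(pathway, "diagnostic_pathway"),
            inherits(harms, "harm_rates"),
            inherits(rule, "surveillance_rule"))
  s <- health_states()
  d <- state$distribution
  N <- state$size
  elig <- invitable_states()

  m <- stats::setNames(numeric(16L), s)
  m[elig] <- d[elig] * N                # persons eligible, by state
  invited <- sum(m)
  screened_s <- m * uptake
  pos_s <- screened_s * positivity
  workup_s <- pos_s * pathway$colonoscopy_compliance
  col_s <- workup_s * (1 - pathway$ctc_fraction_of_workups)
  ctc_s <- workup_s * pathway$ctc_fraction_of_workups

  col_sens <- stats::setNames(numeric(16L), s)
  col_sens["AdenomaLowRisk"] <- pathway$col_sens_low
  col_sens["AdenomaIntHighRisk"] <- pathway$col_sens_inthigh
  col_sens[.preclin] <- pathway$col_sens_crc
  ctc_sens <- stats::setNames(numeric(16L), s)
  ctc_sens["AdenomaLowRisk"] <- pathway$ctc_sens_low
  ctc_sens["AdenomaIntHighRisk"] <- pathway$ctc_sens_inthigh
  ctc_sens[.preclin] <- pathway$ctc_sens_crc

  det_s <- col_s * col_sens + ctc_s * ctc_sens
  det_low <- det_s[["AdenomaLowRisk"]]
  det_ih <- det_s[["AdenomaIntHighRisk"]]
  det_crc <- as.numeric(det_s[.preclin])
  names(det_crc) <- .stages

  # colonoscopies at which polyps were removed
  n_col_polyp <- col_s[["AdenomaLowRisk"]] * pathway$col_sens_low +
    col_s[["AdenomaIntHighRisk"]] * pathway$col_sens_inthigh
  n_col_nopolyp <- sum(col_s) - n_col_polyp
  n_fsig <- if (fsig_exam) sum(screened_s) else 0
  hv <- expected_harms(n_col_polyp, n_col_nopolyp, n_fsig, harms)

  # redistribute detected mass (fraction units)
  out <- state
  dd <- d
  dd["AdenomaLowRisk"] <- dd["AdenomaLowRisk"] - det_low / N
  dd["SurveillanceLowRisk"] <- dd["SurveillanceLowRisk"] + det_low / N
  dd["AdenomaIntHighRisk"] <- dd["AdenomaIntHighRisk"] - det_ih / N
  dd["SurveillanceIntHighRisk"] <- dd["SurveillanceIntHighRisk"] + det_ih / N
  dd[.preclin] <- dd[.preclin] - det_crc / N
  dd["CancerCare"] <- dd["CancerCare"] + sum(det_crc * detect_cure) / N
  out$pending_clinical <- state$pending_clinical +
    det_crc * (1 - detect_cure) / N
  out$distribution <- dd
  out$ever_diagnosed_fraction <- min(
    1, state$ever_diagnosed_fraction + (det_low + det_ih + sum(det_crc)) / N)
  out$surv_queue <- queue_add(
    out$surv_queue,
    intermediate = det_ih / N * (1 - rule$high_risk_fraction),
    high = det_ih / N * rule$high_risk_fraction, rule = rule)

  structure(list(test = test_name,
                 invited = invited, screened = sum(screened_s),
                 positives = sum(pos_s),
                 workup_col = sum(col_s), workup_ctc = sum(ctc_s),
                 detected_low_adenoma_persons = det_low,
                 detected_inthigh_adenoma_persons = det_ih,
                 detected_crc_by_stage = det_crc,
                 n_col_polyp = n_col_polyp, n_col_nopolyp = n_col_nopolyp,
                 n_fsig = n_fsig,
                 harm_bleeds = hv[["bleeds"]],
                 harm_perforations = hv[["perforations"]],
                 harm_perf_deaths = hv[["perf_deaths"]],
                 updated_cohort = out),
            class = "screening_round_result")
}

# Add newly detected int/high-risk mass to the surveillance queues.
# Queue position i holds the mass due a surveillance exam in i years.
queue_add <- function(queue, intermediate, high, rule) {
  put <- function(q, at, mass) {
    if (mass <= 0) return(q)
    if (length(q) < at) q <- c(q, numeric(at - length(q)))
    q[at] <- q[at] + mass
    q
  }
  queue$intermediate <- put(queue$intermediate,
                            rule$interval_years_intermediate, intermediate)
  queue$high <- put(queue$high, rule$interval_years_high, high)
  queue
}

#' Run one screening round on a cohort
#'
#' Superimposes a screening invitation on the cohort: invitation of the
#' alive, never-diagnosed mass; test completion at the profile's uptake;
#' referral of positives (class sensitivity for lesion-bearing mass, one
#' minus specificity for lesion-free mass); diagnostic work-up at
#' colonoscopy compliance, split between colonoscopy and CT colonography;
#' detection at the work-up test's class sensitivity.  Detected adenomas
#' are removed (polypectomy): low-risk persons move to
#' `SurveillanceLowRisk` (no scheduled follow-up, no longer invited),
#' intermediate/high-risk persons move to `SurveillanceIntHighRisk` and
#' enter the surveillance schedule.  Detected CRC moves to the clinical
#' (diagnosed) state of the same stage.  Missed lesions, non-compliant
#' positives and false positives return to their underlying state.
#' Colonoscopy harms use the with-polypectomy perforation rate for
#' colonoscopies at which adenomas were found; an FSIG profile
#' additionally incurs FSIG harms for every screening examination.
#'
#' All outputs are expected counts from the deterministic cohort model;
#' rounding to whole persons happens only in final reports.
#'
#' @param state A [cohort_state()].
#' @param test A [test_profile()].
#' @param pathway A [diagnostic_pathway()].
#' @param harms A [harm_rates()].
#' @param distal_fraction Fraction of neoplasia within reach of a
#'   distal-only test.  Ignored (with a warning if not 1) for
#'   whole-colon tests.
#' @param rule A [surveillance_rule()].
#' @param detect_cure Stage-specific cure fractions for screen-detected
#'   CRC, see [screen_detect_cure()].
#' @return Object of class `screening_round_result`: expected `invited`,
#'   `screened`, `positives`, `workup_col`, `workup_ctc`, detected
#'   persons by lesion class and stage, endoscopy harm expectations, and
#'   the `updated_cohort`.
#' @examples
#' co <- cohort_state(60, 1000, c(0.99, 0, 0, 0.01, rep(0, 12)))
#' fit <- base_case_config()$tests$FIT
#' r <- screen_round(co, fit, diagnostic_pathway(ctc_fraction_of_workups = 0),
#'                   harm_rates())
#' r$positives  # 0.53 * 1000 * (0.01*0.71 + 0.99*0.05)
#' @export
screen_round <- function(state, test, pathway, harms, distal_fraction = 1,
                         rule = surveillance_rule(),
                         detect_cure = screen_detect_cure()) {
  stopifnot(inherits(test, "test_profile"))
  if (distal_fraction < 0 || distal_fraction > 1)
    stop("'distal_fraction' must lie in [0, 1]")
  if (test$reach == "whole_colon" && distal_fraction != 1) {
    warning("'distal_fraction' ignored for a whole-colon test")
    distal_fraction <- 1
  }
  pos <- screening_positivity(test, distal_fraction)
  screen_core(state, test$uptake, pos, pathway, harms, rule,
              fsig_exam = identical(test$name, "FSIG"),
              test_name = test$name, detect_cure = detect_cure)
}

#' Run one gFOBT round with reflex FIT
#'
#' Weak gFOBT positives are re-tested with FIT before referral: only
#' strong positives and FIT-confirmed weak positives proceed to
#' diagnostic work-up.  With `weak_positive_fraction = 0` the result is
#' identical to [screen_round()] with the gFOBT profile.
#'
#' @param state A [cohort_state()].
#' @param gfobt,fit [test_profile()]s for the primary and reflex tests.
#' @param weak_positive_fraction Fraction of gFOBT positives that are
#'   weak positives (re-tested rather than referred).
#' @inheritParams screen_round
#' @return A `screening_round_result` (see [screen_round()]).
#' @export
reflex_gfobt_round <- function(state, gfobt, fit, weak_positive_fraction,
                               pathway, harms, rule = surveillance_rule(),
                               detect_cure = screen_detect_cure()) {
  stopifnot(inherits(gfobt, "test_profile"), inherits(fit, "test_profile"))
  if (weak_positive_fraction < 0 || weak_positive_fraction > 1)
    stop("'weak_positive_fraction' must lie in [0, 1]")
  p1 <- screening_positivity(gfobt, 1)
  p2 <- screening_positivity(fit, 1)
  pos <- p1 * ((1 - weak_positive_fraction) + weak_positive_fraction * p2)
  screen_core(state, gfobt$uptake, pos, pathway, harms, rule,
              fsig_exam = FALSE, test_name = "gFOBT_reflex_FIT",
              detect_cure = detect_cure)
}

#' Run one year of post-polypectomy surveillance on a cohort
#'
#' Advances the surveillance schedule one year and examines the mass
#' falling due: colonoscopy at the diagnostic compliance, split to CT
#' colonography for those unfit.  Exams finding new
#' intermediate/high-risk adenomas (probability `rule$inthigh_yield`)
#' restart the schedule as fresh detections; other attenders return in
#' three years; non-attenders are recalled the next year.  Persons under
#' surveillance remain in the `SurveillanceIntHighRisk` state throughout.
#'
#' @param state A [cohort_state()].
#' @param rule A [surveillance_rule()].
#' @param pathway A [diagnostic_pathway()].
#' @param harms A [harm_rates()].
#' @return A `screening_round_result` whose `workup_col`/`workup_ctc`
#'   are surveillance procedures;
#'   `detected_inthigh_adenoma_persons` counts new surveillance
#'   detections (already-diagnosed persons, so eligibility is unchanged).
#' @export
surveillance_round <- function(state, rule, pathway, harms) {
  stopifnot(inherits(state, "cohort_state"),
            inherits(rule, "surveillance_rule"),
            inherits(pathway, "diagnostic_pathway"),
            inherits(harms, "harm_rates"))
  N <- state$size
  pop_due <- function(q) {
    if (length(q) == 0L) list(due = 0, q = q)
    else list(due = q[1L], q = q[-1L])
  }
  qi <- pop_due(state$surv_queue$intermediate)
  qh <- pop_due(state$surv_queue$high)
  due <- qi$due + qh$due                       # fraction units
  attended <- due * pathway$colonoscopy_compliance
  missed <- due - attended
  n_col <- attended * N * (1 - pathway$ctc_fraction_of_workups)
  n_ctc <- attended * N * pathway$ctc_fraction_of_workups
  found <- attended * rule$inthigh_yield
  hv <- expected_harms(n_col * rule$inthigh_yield,
                       n_col * (1 - rule$inthigh_yield), 0, harms)

  out <- state
  out$surv_queue <- list(intermediate = qi$q, high = qh$q)
  # attenders without new findings: next routine exam in 3 years
  out$surv_queue <- queue_add(
    out$surv_queue, intermediate = attended - found, high = 0,
    rule = surveillance_rule(
      interval_years_intermediate = rule$interval_years_intermediate,
      interval_years_high = rule$interval_years_high,
      high_risk_fraction = rule$high_risk_fraction,
      inthigh_yield = rule$inthigh_yield))
  # new findings restart the schedule as fresh detections
  out$surv_queue <- queue_add(
    out$surv_queue,
    intermediate = found * (1 - rule$high_risk_fraction),
    high = found * rule$high_risk_fraction, rule = rule)
  # non-attenders recalled next year
  out$surv_queue <- queue_add(
    out$surv_queue, intermediate = missed, high = 0,
    rule = surveillance_rule(interval_years_intermediate = 1,
                             interval_years_high = 1,
                             high_risk_fraction = rule$high_risk_fraction,
                             inthigh_yield = rule$inthigh_yield))

  structure(list(test = "surveillance",
                 invited = due * N, screened = attended * N,
                 positives = attended * N,
                 workup_col = n_col, workup_ctc = n_ctc,
                 detected_low_adenoma_persons = 0,
                 detected_inthigh_adenoma_persons = found * N,
                 detected_crc_by_stage = stats::setNames(numeric(4L), .stages),
                 n_col_polyp = n_col * rule$inthigh_yield,
                 n_col_nopolyp = n_col * (1 - rule$inthigh_yield),
                 n_fsig = 0,
                 harm_bleeds = hv[["bleeds"]],
                 harm_perforations = hv[["perforations"]],
                 harm_perf_deaths = hv[["perf_deaths"]],
                 updated_cohort = out),
            class = "screening_round_result")
}

#' @export
print.screening_round_result <- function(x, ...) {
  cat(sprintf("Screening round (%s): %.1f invited, %.1f screened, %.1f positive\n",
              x$test, x$invited, x$screened, x$positives))
  cat(sprintf("  work-ups: %.1f colonoscopy, %.1f CT colonography\n",
              x$workup_col, x$workup_ctc))
  cat(sprintf("  detections: %.1f low-risk adenoma, %.1f int/high-risk adenoma, %.1f CRC\n",
              x$detected_low_adenoma_persons,
              x$detected_inthigh_adenoma_persons,
              sum(x$detected_crc_by_stage)))
  invisible(x)
}
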