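#' CRC work-up and treatment resource accounting
#'
#' Each work-up resource is required by a fixed fraction of
#' screen-detected CRC cases; CT staging applies to every detected case.
#'
#' @param crc_detections_by_stage Numeric vector of detected CRC by stage
#'   (stage only matters through its total here).
#' @param fractions Named list/vector of work-up fractions with entries
#'   `pet`, `mri`, `ct`, `tus`, `preop_rt`, `resections`.
#' @return Named numeric vector of expected counts.
#' @examples
#' account_crc_workup(c(111, 105, 69, 24), crc_workup_fractions())
#' @export
account_crc_workup <- function(crc_detections_by_stage,
                               fractions = crc_workup_fractions()) {
  f <- unlist(fractions)
  need <- c("pet", "mri", "ct", "tus", "preop_rt", "resections")
  if (!all(need %in% names(f)))
    stop("fractions must name: ", paste(need, collapse = ", "))
  if (any(f < 0) || any(f > 1)) stop("work-up fractions must lie in [0, 1]")
  total <- sum(crc_detections_by_stage)
  stats::setNames(total * f[need], need)
}

#' @rdname account_crc_workup
#' @param pet,mri,ct,tus,preop_rt,resections Work-up fractions.
#' @export
crc_workup_fractions <- function(pet = 0.10, mri = 0.36, ct = 1.00,
                                 tus = 0.052, preop_rt = 0.23,
                                 resections = 0.91) {
  list(pet = pet, mri = mri, ct = ct, tus = tus, preop_rt = preop_rt,
       resections = resections)
}

# Ledger column names in report order.
.ledger_fields <- c(
  "kits_sent", "kits_processed", "fsig_done",
  "diagnostic_col", "diagnostic_ctc", "surveillance_col",
  "surveillance_ctc", "pathology_lesions",
  "pet", "mri", "ct", "tus", "preop_rt", "resections",
  "bleeds", "perforations", "perf_deaths",
  "adenoma_persons_low", "adenoma_persons_inthigh", "adenoma_persons_total",
  "crc_I", "crc_II", "crc_III", "crc_IV", "crc_total",
  "crc_cases", "crc_deaths", "alive")

#' Project a screening scenario over the population
#'
#' Runs the cross-sectional whole-population analysis: every single-year
#' age cohort of the pyramid is initialised by natural-history burn-in,
#' then stepped through the programme horizon.  Each calendar year the
#' invitation schedule is applied, screening and surveillance rounds are
#' run for the invited/due cohorts, the cohort ages one Markov cycle, and
#' all resource, harm and outcome expectations are summed across cohorts.
#' Persons diagnosed with cancer or adenomas leave the eligible pool, so
#' later rounds see lower prevalence.
#'
#' @param pyramid A [population_pyramid()].
#' @param model A calibrated `transition_model`.
#' @param scenario A [scenario_spec()].
#' @param config A screening configuration, see [base_case_config()].
#' @param by_cohort If `TRUE`, also return the year x cohort breakdown
#'   of every ledger field.
#' @return An object of class `annual_ledger`: `ledger` is a data.frame
#'   with one row per calendar year and one column per resource/outcome
#'   (fractional expectations; see [report_ledger()] for the rounded
#'   presentation), `scenario` the spec, and optionally `by_cohort` a
#'   3-d array (year x field x cohort).
#' @export
run_scenario <- function(pyramid, model, scenario, config = base_case_config(),
                         by_cohort = FALSE) {
  stopifnot(inherits(pyramid, "population_pyramid"),
            inherits(model, "transition_model"),
            inherits(scenario, "scenario_spec"))
  if (!isTRUE(model$calibrated))
    stop("transition model is an uncalibrated sentinel; ",
         "run calibrate_transitions() first")
  years <- scenario$horizon_years
  cohorts <- init_cohorts(pyramid, model)
  nf <- length(.ledger_fields)
  L <- matrix(0, years, nf, dimnames = list(NULL, .ledger_fields))
  BC <- if (by_cohort)
    array(0, c(years, nf, length(cohorts)),
          dimnames = list(NULL, .ledger_fields, NULL))
  faecal <- scenario$modality %in% c("FIT", "gFOBT_reflex_FIT")
  for (y in seq_len(years)) {
    ages_y <- invited_ages(scenario, y)
    for (i in seq_along(cohorts)) {
      co <- cohorts[[i]]
      row <- stats::setNames(numeric(nf), .ledger_fields)
      # within a calendar year: surveillance exams falling due, then the
      # screening round, then one Markov cycle of natural history.
      # Screen-detected cancers begin care at the end of the cycle (see
      # step_cohort), so newly diagnosed cases by either route face CRC
      # death risk from the next year.
      if (scenario$modality != "none") {
        sv <- surveillance_round(co, config$rule, config$pathway,
                                 config$harms)
        co <- sv$updated_cohort
        row["surveillance_col"] <- sv$workup_col
        row["surveillance_ctc"] <- sv$workup_ctc
        row["bleeds"] <- sv$harm_bleeds
        row["perforations"] <- sv$harm_perforations
        row["perf_deaths"] <- sv$harm_perf_deaths
      }
      if (co$age %in% ages_y) {
        cure <- config$screen_detect_cure
        if (is.null(cure)) cure <- screen_detect_cure()
        r <- switch(scenario$modality,
          FIT = screen_round(co, config$tests$FIT, config$pathway,
                             config$harms, rule = config$rule,
                             detect_cure = cure),
          gFOBT_reflex_FIT = reflex_gfobt_round(
            co, config$tests$gFOBT, config$tests$FIT,
            config$weak_positive_fraction, config$pathway, config$harms,
            rule = config$rule, detect_cure = cure),
          FSIG = screen_round(co, config$tests$FSIG, config$pathway,
                              config$harms,
                              distal_fraction = config$distal_fraction,
                              rule = config$rule, detect_cure = cure))
        co <- r$updated_cohort
        if (faecal) {
          row["kits_sent"] <- r$invited
          row["kits_processed"] <- r$screened
        } else {
          row["fsig_done"] <- r$screened
        }
        row["diagnostic_col"] <- r$workup_col
        row["diagnostic_ctc"] <- r$workup_ctc
        row["adenoma_persons_low"] <- r$detected_low_adenoma_persons
        row["adenoma_persons_inthigh"] <- r$detected_inthigh_adenoma_persons
        row[c("crc_I", "crc_II", "crc_III", "crc_IV")] <-
          r$detected_crc_by_stage
        row["bleeds"] <- row["bleeds"] + r$harm_bleeds
        row["perforations"] <- row["perforations"] + r$harm_perforations
        row["perf_deaths"] <- row["perf_deaths"] + r$harm_perf_deaths
        row["crc_cases"] <- sum(r$detected_crc_by_stage)
      }
      co <- step_cohort(co, model)
      fl <- attr(co, "flows")
      row["alive"] <- co$size * alive_fraction(co)
      row["crc_cases"] <- row["crc_cases"] +
        co$size * sum(fl$clinical_by_stage)
      row["crc_deaths"] <- co$size * fl$crc_deaths
      # derived fields (all linear in the detections of this cohort-year)
      row["adenoma_persons_total"] <- row["adenoma_persons_low"] +
        row["adenoma_persons_inthigh"]
      row["crc_total"] <- sum(row[c("crc_I", "crc_II", "crc_III", "crc_IV")])
      row["pathology_lesions"] <-
        row["adenoma_persons_total"] * config$adenomas_per_person +
        row["crc_total"]
      wk <- account_crc_workup(
        row[c("crc_I", "crc_II", "crc_III", "crc_IV")],
        config$crc_workup_fractions)
      row[names(wk)] <- wk
      cohorts[[i]] <- co
      L[y, ] <- L[y, ] + row
      if (by_cohort) BC[y, , i] <- row
    }
  }
  out <- list(ledger = data.frame(year = seq_len(years), L,
                                  check.names = FALSE),
              scenario = scenario)
  if (by_cohort) out$by_cohort <- BC
  class(out) <- "annual_ledger"
  out
}

#' Round half away from zero
#'
#' Reporting convention for expected counts: 0.5 rounds to 1, -0.5 to -1.
#'
#' @param x Numeric.
#' @return `x` rounded to the nearest integer, ties away from zero.
#' @export
round_half_out <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Present an annual ledger in the standard report layout
#'
#' One row per resource/outcome, one column per programme year, counts
#' rounded half away from zero.  The pathology row is recomputed from the
#' rounded detection counts so that the printed identity
#' `pathology = round(1.9 x adenoma persons) + CRC` holds.
#'
#' @param x An `annual_ledger` from [run_scenario()].
#' @param adenomas_per_person Mean adenomas removed per person with
#'   adenomas (pathology specimens).
#' @return data.frame, rows = ledger fields, columns = `year_1` ...
#' @export
report_ledger <- function(x, adenomas_per_person = 1.9) {
  stopifnot(inherits(x, "annual_ledger"))
  L <- x$ledger
  R <- t(vapply(.ledger_fields, function(f) round_half_out(L[[f]]),
                numeric(nrow(L))))
  colnames(R) <- paste0("year_", L$year)
  R["pathology_lesions", ] <-
    round_half_out(R["adenoma_persons_total", ] * adenomas_per_person) +
    R["crc_total", ]
  data.frame(field = .ledger_fields, R, row.names = NULL,
             check.names = FALSE)
}

#' @export
print.annual_ledger <- function(x, ...) {
  print(x$scenario)
  utils::str(x$ledger, max.level = 1, give.attr = FALSE)
  invisible(x)
}

#' Write or read an annual ledger report
#'
#' Tab-separated report in the rows-by-years layout of
#' [report_ledger()], with `#` header lines recording provenance.
#'
#' @param x An `annual_ledger`.
#' @param path Output file.
#' @param header Character vector of provenance lines (each written
#'   prefixed by `# `).
#' @return `read_ledger_report()` returns the report data.frame.
#' @export
write_ledger_report <- function(x, path, header = character(0)) {
  rep <- report_ledger(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste("#", h), con)
  utils::write.table(rep, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_ledger_report
#' @export
read_ledger_report <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE)
}
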