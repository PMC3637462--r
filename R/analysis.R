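#' One-way sensitivity analysis specification
#'
#' @param parameter One of `"uptake"`, `"test_sensitivity"`,
#'   `"test_specificity"`.
#' @param low,base,high Parameter values (scalars for uptake and
#'   specificity; for sensitivity, named vectors of the class-specific
#'   sensitivities to set jointly, e.g. `c(sens_adenoma = , sens_crc =)`).
#' @return Object of class `sensitivity_spec`.
#' @export
sensitivity_spec <- function(parameter = c("uptake", "test_sensitivity",
                                           "test_specificity"),
                             low, base, high) {
  parameter <- match.arg(parameter)
  if (any(unlist(low) > unlist(base)) || any(unlist(base) > unlist(high)))
    stop("sensitivity values must satisfy low <= base <= high")
  structure(list(parameter = parameter, low = low, base = base,
                 high = high), class = "sensitivity_spec")
}

# Return a config with one parameter of one test set to `value`.
apply_parameter_value <- function(config, test_name, parameter, value) {
  t <- config$tests[[test_name]]
  if (is.null(t)) stop("unknown test: ", test_name)
  if (parameter == "uptake") {
    t$uptake <- as.numeric(value)
  } else if (parameter == "test_specificity") {
    t$specificity <- as.numeric(value)
  } else if (parameter == "test_sensitivity") {
    v <- unlist(value)
    if ("sens_adenoma" %in% names(v)) {
      t$sens_low_adenoma <- v[["sens_adenoma"]]
      t$sens_inthigh_adenoma <- v[["sens_adenoma"]]
    }
    if ("sens_low_adenoma" %in% names(v))
      t$sens_low_adenoma <- v[["sens_low_adenoma"]]
    if ("sens_inthigh_adenoma" %in% names(v))
      t$sens_inthigh_adenoma <- v[["sens_inthigh_adenoma"]]
    if ("sens_crc" %in% names(v)) t$sens_crc <- v[["sens_crc"]]
  } else stop("unknown parameter: ", parameter)
  config$tests[[test_name]] <- do.call(test_profile, unclass(t))
  config
}

#' One-way sensitivity analysis
#'
#' Re-runs a full scenario projection with the named parameter of the
#' scenario's screening test set to its low, base and high values, all
#' else fixed.  For the gFOBT-with-reflex-FIT pathway, FIT parameters
#' vary jointly with the test under study when the reflex stage is
#' active.
#'
#' @param pyramid A [population_pyramid()].
#' @param model A calibrated `transition_model`.
#' @param scenario A [scenario_spec()].
#' @param spec A [sensitivity_spec()].
#' @param config Base screening configuration.
#' @param fields Ledger fields to tabulate.
#' @return Object of class `sensitivity_result`: `table` is a data.frame
#'   `year` x `field` x (`low`, `base`, `high`); `ledgers` holds the
#'   three full [run_scenario()] ledgers.
#' @export
one_way_sensitivity <- function(pyramid, model, scenario, spec,
                                config = base_case_config(),
                                fields = c("diagnostic_col", "crc_total")) {
  stopifnot(inherits(spec, "sensitivity_spec"),
            inherits(scenario, "scenario_spec"))
  test_name <- switch(scenario$modality,
                      FIT = "FIT", FSIG = "FSIG",
                      gFOBT_reflex_FIT = "gFOBT",
                      stop("sensitivity analysis needs a screening scenario"))
  run_at <- function(value) {
    cfg <- apply_parameter_value(config, test_name, spec$parameter, value)
    if (scenario$modality == "gFOBT_reflex_FIT" &&
        config$weak_positive_fraction > 0 &&
        spec$parameter != "uptake") {
      cfg <- apply_parameter_value(cfg, "FIT", spec$parameter, value)
    }
    run_scenario(pyramid, model, scenario, cfg)
  }
  ledgers <- list(low = run_at(spec$low), base = run_at(spec$base),
                  high = run_at(spec$high))
  tab <- do.call(rbind, lapply(fields, function(f) {
    data.frame(year = ledgers$base$ledger$year, field = f,
               low = ledgers$low$ledger[[f]],
               base = ledgers$base$ledger[[f]],
               high = ledgers$high$ledger[[f]])
  }))
  structure(list(table = tab, ledgers = ledgers, spec = spec,
                 scenario = scenario),
            class = "sensitivity_result")
}

#' Percent change, rounded to the nearest integer percent
#'
#' Reporting convention for sensitivity-analysis summaries.
#'
#' @param value,reference Numeric.
#' @return `round(100 * (value / reference - 1))`.
#' @export
percent_change <- function(value, reference) {
  round_half_out(100 * (value / reference - 1))
}

#' Compare a screening scenario against no screening
#'
#' Runs the scenario and a no-screening policy on identical inputs and
#' differences the population CRC case and death counts per year.
#' Cases averted are negative in early years: screening brings forward
#' diagnoses, so total diagnosed cases initially exceed the no-screening
#' arm; deaths averted emerge as screen-detection at earlier stages and
#' adenoma removal take effect.
#'
#' @param pyramid A [population_pyramid()].
#' @param model A calibrated `transition_model` (same model for both
#'   arms).
#' @param scenario A [scenario_spec()].
#' @param config Screening configuration.
#' @return Object of class `relative_result`: data.frame `comparison`
#'   with per-year `cases_with_screening`, `cases_no_screening`,
#'   `deaths_with_screening`, `deaths_no_screening`, `cases_averted`,
#'   `deaths_averted`; plus the two ledgers.
#' @export
relative_vs_no_screening <- function(pyramid, model, scenario,
                                     config = base_case_config()) {
  with_scr <- run_scenario(pyramid, model, scenario, config)
  none <- scenario_spec("none", horizon_years = scenario$horizon_years)
  without <- run_scenario(pyramid, model, none, config)
  cmp <- data.frame(
    year = with_scr$ledger$year,
    cases_with_screening = with_scr$ledger$crc_cases,
    cases_no_screening = without$ledger$crc_cases,
    deaths_with_screening = with_scr$ledger$crc_deaths,
    deaths_no_screening = without$ledger$crc_deaths)
  cmp$cases_averted <- cmp$cases_no_screening - cmp$cases_with_screening
  cmp$deaths_averted <- cmp$deaths_no_screening - cmp$deaths_with_screening
  structure(list(comparison = cmp, scenario = scenario,
                 with_screening = with_scr, no_screening = without),
            class = "relative_result")
}

#' @export
print.relative_result <- function(x, ...) {
  print(x$scenario)
  d <- x$comparison
  cat(sprintf("Year 10: %.0f cases averted, %.0f deaths averted vs no screening\n",
              round_half_out(d$cases_averted[nrow(d)]),
              round_half_out(d$deaths_averted[nrow(d)])))
  invisible(x)
}

#' Plot a relative-analysis trajectory
#'
#' Differences in CRC cases and deaths (screening minus no screening)
#' per programme year, one panel per outcome.
#'
#' @param x A `relative_result`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.relative_result <- function(x, ...) {
  d <- x$comparison
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (what in c("cases", "deaths")) {
    diff <- d[[paste0(what, "_with_screening")]] -
      d[[paste0(what, "_no_screening")]]
    graphics::plot(d$year, diff, type = "b", pch = 19,
                   xlab = "Year of programme",
                   ylab = sprintf("Difference in CRC %s vs no screening",
                                  what), ...)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}

#' Plot a one-way sensitivity analysis
#'
#' For each tabulated field, the base-case trajectory with the low/high
#' envelope, in the style of a tornado-free year-profile plot.
#'
#' @param x A `sensitivity_result`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.sensitivity_result <- function(x, ...) {
  flds <- unique(x$table$field)
  op <- graphics::par(mfrow = c(1, length(flds)))
  on.exit(graphics::par(op))
  for (f in flds) {
    d <- x$table[x$table$field == f, ]
    graphics::plot(d$year, d$base, type = "b", pch = 18,
                   ylim = range(d[c("low", "base", "high")]),
                   xlab = "Year of programme", ylab = f, ...)
    graphics::points(d$year, d$low, pch = "-", cex = 2)
    graphics::points(d$year, d$high, pch = "-", cex = 2)
  }
  invisible(x)
}
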