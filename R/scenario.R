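#' Screening scenario specification
#'
#' The three core programmes are biennial gFOBT (with reflex FIT) at ages
#' 55-74, biennial FIT at 55-74, and once-only FSIG at age 60.
#' Alternative FIT roll-outs restrict the age range (55-64) or stagger
#' the introduction of two-year age bands ("medium" reaches the full age
#' range in year five, "slow" in year ten).
#'
#' @param modality One of `"gFOBT_reflex_FIT"`, `"FIT"`, `"FSIG"`,
#'   `"none"`.
#' @param age_low,age_high Eligible age range for faecal-test screening.
#' @param frequency `"biennial"` or `"once_only"` (FSIG must be
#'   once-only).
#' @param rollout `"base"`, `"age_restricted"`, `"medium"` or `"slow"`.
#' @param horizon_years Projection horizon (the analyses use 10).
#' @param fsig_age Single screening age for FSIG.
#' @return Object of class `scenario_spec`.
#' @examples
#' scenario_spec("FIT")                       # base-case biennial FIT 55-74
#' scenario_spec("FIT", rollout = "slow")     # staggered introduction
#' @export
scenario_spec <- function(modality = c("FIT", "gFOBT_reflex_FIT", "FSIG",
                                       "none"),
                          age_low = 55L, age_high = 74L,
                          frequency = c("biennial", "once_only"),
                          rollout = c("base", "age_restricted", "medium",
                                      "slow"),
                          horizon_years = 10L, fsig_age = 60L) {
  modality <- match.arg(modality)
  rollout <- match.arg(rollout)
  frequency <- if (missing(frequency) && modality == "FSIG") "once_only"
               else match.arg(frequency)
  if (modality == "FSIG" && frequency != "once_only")
    stop("FSIG screening is once-only at a single age")
  if (age_low > age_high) stop("age_low must not exceed age_high")
  if (rollout == "age_restricted") age_high <- min(age_high, 64L)
  structure(list(modality = modality, age_low = as.integer(age_low),
                 age_high = as.integer(age_high), frequency = frequency,
                 rollout = rollout,
                 horizon_years = as.integer(horizon_years),
                 fsig_age = as.integer(fsig_age)),
            class = "scenario_spec")
}

#' Ages invited in a given programme year
#'
#' Encodes the invitation schedules.  Biennial screening invites half of
#' each two-year age band each year: ages at an even offset from
#' `age_low` are invited every year, so each individual is re-invited
#' every second year as they age through the range.  The medium roll-out
#' starts two-year bands at ages 55 and 65 in year one and adds the next
#' band at each anchor yearly (full range by year five); the slow
#' roll-out starts at age 55 only (full range by year ten).  FSIG invites
#' the single screening age every year, so each person is invited
#' exactly once, on reaching that age.
#'
#' @param scenario A [scenario_spec()].
#' @param year Programme year, 1-based.
#' @return Integer vector of invited ages (possibly empty).
#' @export
invited_ages <- function(scenario, year) {
  stopifnot(inherits(scenario, "scenario_spec"))
  year <- as.integer(year)
  if (year < 1L || year > scenario$horizon_years)
    stop("year must lie in 1..", scenario$horizon_years)
  if (scenario$modality == "none") return(integer(0))
  if (scenario$modality == "FSIG") return(scenario$fsig_age)
  lo <- scenario$age_low
  hi <- scenario$age_high
  all_even <- seq(lo, hi, by = 2L)      # even offsets from age_low
  if (scenario$rollout %in% c("base", "age_restricted")) return(all_even)
  if (scenario$rollout == "slow") {
    return(all_even[all_even <= lo + 2L * (year - 1L)])
  }
  # medium: two anchors, lo and the range midpoint (55 and 65)
  anchor2 <- lo + 10L
  block1 <- seq(lo, min(anchor2 - 1L, hi), by = 2L)
  block2 <- if (anchor2 <= hi) seq(anchor2, hi, by = 2L) else integer(0)
  sort(c(block1[block1 <= lo + 2L * (year - 1L)],
         block2[block2 <= anchor2 + 2L * (year - 1L)]))
}

#' @rdname invited_ages
#' @param age Age in years.
#' @return `invitation_schedule()`: logical, whether this age is invited
#'   this year.
#' @export
invitation_schedule <- function(scenario, year, age) {
  age %in% invited_ages(scenario, year)
}

#' @export
print.scenario_spec <- function(x, ...) {
  if (x$modality == "none") {
    cat("Scenario: no screening\n")
  } else if (x$modality == "FSIG") {
    cat(sprintf("Scenario: once-only FSIG at age %d\n", x$fsig_age))
  } else {
    cat(sprintf("Scenario: biennial %s at ages %d-%d (%s roll-out)\n",
                x$modality, x$age_low, x$age_high, x$rollout))
  }
  invisible(x)
}
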