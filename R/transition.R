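#' Build the age-banded transition model
#'
#' Assembles one row-stochastic one-year transition matrix per age band
#' over the 16-state space of [health_states()].  Within a band, rates
#' are evaluated at the band midpoint.  The two death states are
#' absorbing; death from other causes competes with every disease
#' transition.
#'
#' @param params An [nh_params()] object.
#' @param age_breaks Integer vector of band boundaries covering ages
#'   30-100 without gaps (default 5-year bands).
#' @param calibrated Logical flag recording whether `params` came from
#'   calibration (or are otherwise trusted values).  Population
#'   projections refuse to run on an uncalibrated sentinel model.
#' @return An object of class `transition_model`: list with `age_bands`
#'   (data.frame of `lower`, `upper`), `matrices` (one 16x16 matrix per
#'   band), `cycle_length` (1 year), `params` and `calibrated`.
#' @examples
#' m <- build_transition_model(nh_params())
#' all(abs(rowSums(m$matrices[[1]]) - 1) < 1e-12)
#' @export
build_transition_model <- function(params, age_breaks = seq(30, 100, by = 5),
                                   calibrated = TRUE) {
  validate_nh_params(params)
  age_breaks <- as.integer(age_breaks)
  if (age_breaks[1L] != 30L || age_breaks[length(age_breaks)] != 100L ||
      any(diff(age_breaks) <= 0))
    stop("'age_breaks' must increase from 30 to 100 without gaps")
  nb <- length(age_breaks) - 1L
  bands <- data.frame(lower = age_breaks[-(nb + 1L)],
                      upper = age_breaks[-1L] - 1L)
  mats <- vector("list", nb)
  for (b in seq_len(nb)) {
    mid <- (bands$lower[b] + bands$upper[b]) / 2
    q_oth <- band_other_mortality(params, bands$lower[b], bands$upper[b])
    mats[[b]] <- one_year_matrix(params, mid, q_oth)
  }
  m <- structure(list(age_bands = bands, matrices = mats,
                      cycle_length = 1, params = params,
                      calibrated = isTRUE(calibrated)),
                 class = "transition_model")
  validate_transition_model(m)
  m
}

# Mean other-cause mortality over a band (ages are 30-99 inclusive).
band_other_mortality <- function(params, lower, upper) {
  idx <- (max(lower, 30L):min(upper, 99L)) - 29L
  mean(params$other_cause_mortality[idx])
}

# One-year transition matrix at a representative age.  Other-cause death
# competes proportionally: disease exits are scaled by (1 - q_oth).
one_year_matrix <- function(params, age, q_oth) {
  s <- health_states()
  M <- matrix(0, 16L, 16L, dimnames = list(s, s))
  alive_row <- function(from, to, p) {
    p <- p * (1 - q_oth)
    stopifnot(sum(p) <= 1 + 1e-12)
    M[from, to] <<- p
    M[from, "OtherDeath"] <<- q_oth
    M[from, from] <<- M[from, from] + 1 - q_oth - sum(p)
    invisible(NULL)
  }
  onset <- min(params$onset_base * exp(params$onset_slope * (age - 55)), 1)
  alive_row("Normal", "AdenomaLowRisk", onset)
  alive_row("AdenomaLowRisk", "AdenomaIntHighRisk", params$low_to_inthigh)
  alive_row("AdenomaIntHighRisk", "PreclinicalCRC_I", params$inthigh_to_crc)
  for (i in 1:4) {
    to <- c(if (i < 4) .preclin[i + 1L], .clinical[i])
    pr <- c(if (i < 4) params$progression[i], params$presentation[i])
    alive_row(.preclin[i], to, pr)
  }
  for (i in 1:4) {
    # CRC death is not discounted by the other-cause competition: case
    # fatality already measures death from the cancer itself.
    f <- params$fatality[i]
    r <- params$remission[i] * max(1 - q_oth - f, 0)
    M[.clinical[i], "CRCDeath"] <- f
    M[.clinical[i], "OtherDeath"] <- q_oth
    M[.clinical[i], "CancerCare"] <- r
    M[.clinical[i], .clinical[i]] <- 1 - f - q_oth - r
    if (M[.clinical[i], .clinical[i]] < 0)
      stop("fatality + other-cause mortality exceed 1 in clinical stage ",
           .stages[i])
  }
  alive_row("SurveillanceLowRisk", character(0), numeric(0))
  alive_row("SurveillanceIntHighRisk", character(0), numeric(0))
  alive_row("CancerCare", character(0), numeric(0))
  M["CRCDeath", "CRCDeath"] <- 1
  M["OtherDeath", "OtherDeath"] <- 1
  M
}

#' Validate a transition model
#'
#' Checks row-stochasticity (to 1e-12), probability bounds, absorbing
#' death states, and that other-cause mortality is non-decreasing across
#' age bands.
#'
#' @param model A `transition_model`.
#' @return The model, invisibly; otherwise an error naming the offending
#'   state and age band.
#' @export
validate_transition_model <- function(model) {
  stopifnot(inherits(model, "transition_model"))
  s <- health_states()
  q_prev <- -Inf
  for (b in seq_along(model$matrices)) {
    M <- model$matrices[[b]]
    band <- sprintf("%d-%d", model$age_bands$lower[b], model$age_bands$upper[b])
    if (any(M < -1e-15) || any(M > 1 + 1e-15))
      stop("transition probabilities outside [0,1] in age band ", band)
    dev <- abs(rowSums(M) - 1)
    if (any(dev > 1e-9)) {
      bad <- s[which.max(dev)]
      stop(sprintf("row for state '%s' in age band %s sums to 1 %+.3g",
                   bad, band, max(dev) * sign(sum(M[bad, ]) - 1)))
    }
    for (a in absorbing_states())
      if (M[a, a] != 1 || sum(M[a, ]) != 1)
        stop("absorbing state '", a, "' is not absorbing in age band ", band)
    q_b <- M["Normal", "OtherDeath"]
    if (q_b < q_prev - 1e-12)
      stop("other-cause mortality decreases entering age band ", band)
    q_prev <- q_b
  }
  invisible(model)
}

# Index of the age band containing `age` (age >= 100 returns NA).
band_index <- function(model, age) {
  b <- findInterval(age, c(model$age_bands$lower, 100L),
                    rightmost.closed = FALSE)
  if (b < 1L || b > nrow(model$age_bands)) NA_integer_ else b
}

#' Cohort state
#'
#' A closed cohort of persons of a single age, described by its expected
#' distribution over the health states.  `surv_queue` tracks, for the
#' post-polypectomy surveillance population, the mass due a surveillance
#' colonoscopy in 0, 1, 2, ... years (split by intermediate vs high-risk
#' adenoma history).
#'
#' @param age Age in years.
#' @param size Number of persons the cohort represents.
#' @param distribution Nonnegative vector over [health_states()] summing
#'   to 1.  A scalar-free default puts everyone in `Normal`.
#' @return An object of class `cohort_state`.
#' @export
cohort_state <- function(age, size,
                         distribution = c(1, rep(0, 15L))) {
  d <- as.numeric(distribution)
  if (length(d) != 16L) stop("distribution must have 16 elements")
  if (any(d < -1e-12)) stop("distribution must be nonnegative")
  if (abs(sum(d) - 1) > 1e-9)
    stop("distribution must sum to 1 (deviation ",
         format(sum(d) - 1), ")")
  names(d) <- health_states()
  structure(list(age = age, size = size, distribution = d,
                 ever_diagnosed_fraction = sum(d[diagnosed_states()]),
                 surv_queue = list(intermediate = numeric(0),
                                   high = numeric(0)),
                 # screen-detected CRC mass awaiting entry into the
                 # clinical states at the end of the current cycle
                 pending_clinical = stats::setNames(numeric(4L), .stages)),
            class = "cohort_state")
}

#' @export
print.cohort_state <- function(x, ...) {
  cat(sprintf("Cohort: age %s, %s persons, %.1f%% alive, %.2f%% ever diagnosed\n",
              format(x$age), format(x$size), 100 * alive_fraction(x),
              100 * x$ever_diagnosed_fraction))
  invisible(x)
}

#' Alive fraction of a cohort
#' @param state A [cohort_state()].
#' @return Fraction of the cohort not in a death state.
#' @export
alive_fraction <- function(state) {
  1 - sum(state$distribution[absorbing_states()])
}

#' Advance a cohort one Markov cycle
#'
#' Multiplies the cohort distribution by the age-appropriate transition
#' matrix and increments age by one year.  Cohorts aged 100 or over exit
#' the model: all remaining alive mass is sent to `OtherDeath` and the
#' terminal state is returned unchanged thereafter.
#'
#' @param state A [cohort_state()].
#' @param model A `transition_model` from [build_transition_model()].
#' @return The cohort one cycle later.  The attribute `"flows"` carries
#'   the expected per-person flows of this cycle: `clinical_by_stage`
#'   (new clinical presentations, stages I-IV), `crc_deaths` and
#'   `other_deaths`.
#' @export
step_cohort <- function(state, model) {
  stopifnot(inherits(state, "cohort_state"),
            inherits(model, "transition_model"))
  d <- state$distribution
  if (state$age >= 100) {
    alive <- setdiff(health_states(), absorbing_states())
    d["OtherDeath"] <- d["OtherDeath"] + sum(d[alive]) +
      sum(state$pending_clinical)
    d[alive] <- 0
    out <- state
    out$age <- state$age + model$cycle_length
    out$distribution <- d
    out$pending_clinical[] <- 0
    attr(out, "flows") <- list(clinical_by_stage = numeric(4L),
                               crc_deaths = 0, other_deaths = 0)
    return(out)
  }
  b <- band_index(model, state$age)
  if (is.na(b)) stop("cohort age ", state$age, " outside model coverage")
  M <- model$matrices[[b]]
  d_new <- as.numeric(d %*% M)
  names(d_new) <- health_states()
  # cancers screen-detected during this cycle begin care at its end:
  # they face CRC death risk from the next cycle, the same convention
  # as cancers presenting clinically during the cycle
  d_new[.clinical] <- d_new[.clinical] + state$pending_clinical
  clin <- vapply(1:4, function(i) {
    sum(d[setdiff(health_states(), .clinical[i])] *
          M[setdiff(health_states(), .clinical[i]), .clinical[i]])
  }, numeric(1))
  crc_d <- sum(d * M[, "CRCDeath"]) - d[["CRCDeath"]]
  oth_d <- sum(d * M[, "OtherDeath"]) - d[["OtherDeath"]]
  out <- state
  out$age <- state$age + model$cycle_length
  out$distribution <- d_new
  out$pending_clinical[] <- 0
  # expected new diagnoses this cycle (clinical presentation)
  out$ever_diagnosed_fraction <-
    min(1, state$ever_diagnosed_fraction + sum(clin))
  # age the surveillance queues, applying other-cause attrition
  surv <- 1 - M["SurveillanceIntHighRisk", "OtherDeath"]
  out$surv_queue <- lapply(state$surv_queue, function(q) q * surv)
  attr(out, "flows") <- list(clinical_by_stage = clin,
                             crc_deaths = crc_d, other_deaths = oth_d)
  out
}

# Distribution of a single birth cohort at every age 30..99 under pure
# natural history (burn-in from all-Normal at 30).  Returns a 70 x 16
# matrix plus per-age flow rates; row a is the state of the cohort on
# reaching age 29 + a, flows are those of the year starting there.
natural_history_sweep <- function(model) {
  s <- health_states()
  occ <- matrix(0, 70L, 16L, dimnames = list(30:99, s))
  clin <- matrix(0, 70L, 4L, dimnames = list(30:99, .stages))
  crc_d <- numeric(70L)
  oth_d <- numeric(70L)
  st <- cohort_state(30, 1)
  for (a in 1:70) {
    occ[a, ] <- st$distribution
    st <- step_cohort(st, model)
    fl <- attr(st, "flows")
    clin[a, ] <- fl$clinical_by_stage
    crc_d[a] <- fl$crc_deaths
    oth_d[a] <- fl$other_deaths
  }
  list(occupancy = occ, clinical = clin, crc_deaths = crc_d,
       other_deaths = oth_d)
}

#' Natural-history incidence and mortality trace
#'
#' Runs every cohort of a population pyramid through the natural-history
#' model (no screening) and reports, per calendar year, the expected
#' number of new clinical CRC diagnoses by stage and of CRC deaths,
#' both as counts and as rates per 100,000 alive persons.
#'
#' Cohorts are initialised at their pyramid age by burn-in from age 30
#' (all normal epithelium), conditioned on being alive, so year-one rates
#' are the model's cross-sectional age-specific rates.
#'
#' @param pyramid A [population_pyramid()].
#' @param model A `transition_model`.
#' @param years Number of calendar years to project (>= 1).
#' @return data.frame with columns `year`, `alive`, `incidence_I` ..
#'   `incidence_IV`, `incidence_total`, `crc_deaths`, and the
#'   corresponding `*_rate` columns per 100,000 alive.
#' @export
natural_history_trace <- function(pyramid, model, years) {
  stopifnot(inherits(model, "transition_model"))
  if (!inherits(pyramid, "population_pyramid"))
    stop("'pyramid' must be a population_pyramid")
  if (sum(pyramid$counts) <= 0) stop("population pyramid is empty")
  years <- as.integer(years)
  stopifnot(years >= 1L)
  cohorts <- init_cohorts(pyramid, model)
  inc <- matrix(0, years, 4L, dimnames = list(NULL, .stages))
  inc_tot <- numeric(years)
  deaths <- numeric(years)
  alive <- numeric(years)
  for (y in seq_len(years)) {
    for (i in seq_along(cohorts)) {
      co <- step_cohort(cohorts[[i]], model)
      fl <- attr(co, "flows")
      alive[y] <- alive[y] + co$size * alive_fraction(co)
      inc[y, ] <- inc[y, ] + co$size * fl$clinical_by_stage
      inc_tot[y] <- inc_tot[y] + co$size * sum(fl$clinical_by_stage)
      deaths[y] <- deaths[y] + co$size * fl$crc_deaths
      cohorts[[i]] <- co
    }
  }
  out <- data.frame(year = seq_len(years), alive = alive)
  for (i in 1:4) out[[paste0("incidence_", .stages[i])]] <- inc[, i]
  out$incidence_total <- inc_tot
  out$crc_deaths <- deaths
  rate <- function(x) ifelse(alive > 0, 1e5 * x / alive, 0)
  for (i in 1:4)
    out[[paste0("incidence_", .stages[i], "_rate")]] <- rate(inc[, i])
  out$incidence_total_rate <- rate(out$incidence_total)
  out$crc_mortality_rate <- rate(deaths)
  out
}

# Initialise one cohort_state per pyramid age via the burn-in sweep,
# conditioning each distribution on being alive at that age.
init_cohorts <- function(pyramid, model) {
  sweep <- natural_history_sweep(model)
  lapply(seq_along(pyramid$age), function(i) {
    a <- pyramid$age[i]
    d <- sweep$occupancy[a - 29L, ]
    d[absorbing_states()] <- 0
    if (sum(d) <= 0) d["Normal"] <- 1 else d <- d / sum(d)
    cohort_state(a, pyramid$counts[i], d)
  })
}

#' Serialize a transition model to delimited text
#'
#' Matrices are written in long form (`age_low`, `age_high`, `from`,
#' `to`, `prob`), omitting zero entries.
#'
#' @param model A `transition_model`.
#' @param path Output file.
#' @return `path`, invisibly; `read_transition_matrices()` returns the
#'   long-form data.frame (the matrices as data; rebuilding a model
#'   object requires the parameter file, see [write_nh_params()]).
#' @export
write_transition_matrices <- function(model, path) {
  rows <- do.call(rbind, lapply(seq_along(model$matrices), function(b) {
    M <- model$matrices[[b]]
    idx <- which(M != 0, arr.ind = TRUE)
    data.frame(age_low = model$age_bands$lower[b],
               age_high = model$age_bands$upper[b],
               from = rownames(M)[idx[, 1]], to = colnames(M)[idx[, 2]],
               prob = M[idx])
  }))
  utils::write.csv(rows[order(rows$age_low, rows$from, rows$to), ],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transition_matrices
#' @export
read_transition_matrices <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
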