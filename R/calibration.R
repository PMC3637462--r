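#' Model-predicted incidence and mortality rates by age band
#'
#' Cross-sectional age-specific rates implied by a transition model:
#' a unit cohort is swept from age 30 (all normal epithelium) to 99 and
#' the one-year flows into the clinical CRC states (incidence, by stage)
#' and into CRC death (mortality) are expressed per 100,000 alive
#' persons, then aggregated to age bands weighting each single year of
#' age by the pyramid population.
#'
#' @param model A `transition_model`.
#' @param pyramid A [population_pyramid()].
#' @param age_breaks Band boundaries for aggregation.
#' @return data.frame with columns `age_low`, `age_high`, `measure`,
#'   `stage`, `rate`.
#' @export
predicted_rates <- function(model, pyramid, age_breaks = seq(30, 100, by = 5)) {
  stopifnot(inherits(model, "transition_model"),
            inherits(pyramid, "population_pyramid"))
  sw <- natural_history_sweep(model)
  alive <- 1 - rowSums(sw$occupancy[, absorbing_states(), drop = FALSE])
  # per-alive-person flow rates at each single year of age
  inc_rate <- sw$clinical / pmax(alive, 1e-300)
  mort_rate <- sw$crc_deaths / pmax(alive, 1e-300)
  nb <- length(age_breaks) - 1L
  rows <- vector("list", nb)
  for (b in seq_len(nb)) {
    lo <- age_breaks[b]
    hi <- age_breaks[b + 1L] - 1L
    idx <- (lo:min(hi, 99L)) - 29L
    wts <- pyramid$counts[idx]
    if (sum(wts) <= 0) wts <- rep(1, length(idx))
    wmean <- function(x) sum(x * wts) / sum(wts)
    rows[[b]] <- data.frame(
      age_low = lo, age_high = hi,
      measure = c(rep("incidence", 4L), "mortality"),
      stage = c(.stages, NA_character_),
      rate = 1e5 * c(vapply(1:4, function(s) wmean(inc_rate[idx, s]),
                            numeric(1)),
                     wmean(mort_rate[idx])))
  }
  do.call(rbind, rows)
}

#' Calibration goodness-of-fit objective
#'
#' Weighted relative least squares between model-predicted and target
#' rates: `sum(w * ((predicted - target) / max(target, eps))^2)`.
#' Relative errors put incidence and mortality, and young and old bands,
#' on comparable scales; `eps` (0.1 per 100,000) guards zero targets.
#'
#' @param params An [nh_params()] parameter set to evaluate.
#' @param targets Calibration targets (see [make_targets()],
#'   [read_targets()]).
#' @param pyramid A [population_pyramid()].
#' @param age_breaks Band boundaries (must match the targets).
#' @param eps Zero-target guard, in rate units (per 100,000).
#' @return Nonnegative scalar.
#' @export
calibration_objective <- function(params, targets, pyramid,
                                  age_breaks = seq(30, 100, by = 5),
                                  eps = 0.1) {
  sum(calibration_residuals(params, targets, pyramid, age_breaks, eps)^2)
}

# Residual vector whose sum of squares is the calibration objective.
# Parameter points where competing exits from a state would sum above 1
# (an infeasible chain) get a large constant residual, so the optimiser
# backs away from them.
calibration_residuals <- function(params, targets, pyramid, age_breaks,
                                  eps = 0.1) {
  viol <- feasibility_violation(params)
  if (viol > 0) return(rep(1e3 * (1 + 10 * viol), nrow(targets)))
  model <- tryCatch(
    build_transition_model(params, age_breaks = age_breaks),
    error = function(e) NULL)
  if (is.null(model)) return(rep(1e4, nrow(targets)))
  pred <- predicted_rates(model, pyramid, age_breaks)
  key <- function(d) paste(d$age_low, d$measure,
                           ifelse(is.na(d$stage), "", d$stage))
  m <- match(key(targets), key(pred))
  if (anyNA(m))
    stop("targets contain age bands or measures the model does not predict")
  w <- if (is.null(targets$weight)) rep(1, nrow(targets)) else targets$weight
  if (any(w < 0)) stop("target weights must be nonnegative")
  sqrt(w) * (pred$rate[m] - targets$rate) / pmax(targets$rate, eps)
}

# Total amount by which competing exits from any state exceed one
# (0 when the parameter set yields a valid chain).
feasibility_violation <- function(params, margin = 0.999) {
  excess <- c(params$presentation[1:3] + params$progression - margin,
              params$presentation[4L] - margin,
              params$fatality + params$remission - margin)
  sum(pmax(excess, 0))
}

# Scale competing preclinical exits so each pair sums below `margin`.
project_feasible <- function(v, margin = 0.95) {
  for (s in 1:3) {
    tot <- v[[paste0("pres_", .stages[s])]] + v[[4L + s]]
    if (tot > margin) {
      sc <- margin / tot
      v[[paste0("pres_", .stages[s])]] <- v[[paste0("pres_", .stages[s])]] * sc
      v[[4L + s]] <- v[[4L + s]] * sc
    }
  }
  v
}

#' Calibrate natural-history transition probabilities
#'
#' Estimates the unobservable transition parameters (adenoma onset level
#' and age slope, adenoma progression, preclinical stage dwell,
#' stage-specific clinical presentation, stage-specific case fatality;
#' 15 parameters) by fitting model-predicted incidence by stage and CRC
#' mortality to target rates.  The objective is the weighted relative
#' least squares of [calibration_objective()], minimised by bounded
#' Levenberg-Marquardt on the residual vector with a seeded multistart:
#' the first start is `init`, further starts are log-normal perturbations
#' of it (deterministic given `seed`), and the best local minimiser is
#' returned.  Other-cause mortality and remission rates are fixed inputs
#' taken from `init`.
#'
#' @param targets Calibration targets data.frame.
#' @param pyramid A [population_pyramid()].
#' @param init An [nh_params()] starting point (also supplies the fixed
#'   inputs).
#' @param lower,upper Named bounds on the 15 fitted parameters (defaults
#'   span the plausible epidemiological range).
#' @param seed Integer; fixes the multistart order.
#' @param n_starts Number of starts (1 = plain local search).
#' @param max_eval Residual-evaluation budget across all starts; if
#'   exhausted before convergence the best-so-far parameters are
#'   returned with `converged = FALSE` and a warning.
#' @param age_breaks Band boundaries (must match the targets).
#' @return Object of class `calibration_result`: `fitted` ([nh_params()]),
#'   `model` (calibrated `transition_model`), `objective_value`,
#'   `predicted` (rates at the fit), `converged`, `evaluations`.
#' @export
calibrate_transitions <- function(targets, pyramid, init = nh_params(),
                                  lower = NULL, upper = NULL, seed = 1L,
                                  n_starts = 3L, max_eval = 4000L,
                                  age_breaks = seq(30, 100, by = 5)) {
  validate_nh_params(init)
  v0 <- params_to_vector(init)
  if (is.null(lower))
    lower <- stats::setNames(c(1e-4, 0.0, 0.001, 0.001, rep(0.01, 3),
                               rep(0.01, 4), rep(0.001, 4)),
                             .fitted_par_names)
  if (is.null(upper))
    upper <- stats::setNames(c(0.10, 0.15, 0.5, 0.5, rep(0.95, 3),
                               rep(0.98, 4), rep(0.9, 4)),
                             .fitted_par_names)
  lower <- lower[.fitted_par_names]
  upper <- upper[.fitted_par_names]
  if (any(v0 < lower - 1e-12) || any(v0 > upper + 1e-12))
    stop("'init' lies outside the parameter bounds")

  evals <- 0L
  resid_fn <- function(v) {
    evals <<- evals + 1L
    p <- vector_to_params(v, init)
    calibration_residuals(p, targets, pyramid, age_breaks)
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  starts <- list(project_feasible(v0))
  if (n_starts > 1L)
    for (k in seq_len(n_starts - 1L))
      starts[[k + 1L]] <- project_feasible(
        pmin(pmax(v0 * exp(stats::rnorm(15L, 0, 0.15)), lower), upper))

  best <- NULL
  converged <- FALSE
  for (st in starts) {
    if (evals >= max_eval) break
    fit <- minpack.lm::nls.lm(
      par = st, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = 200L, maxfev = max(50L, max_eval - evals),
        ftol = 1e-12, ptol = 1e-10))
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (fit$info %in% 1:4) converged <- TRUE
    if (best$deviance < 1e-14) break
  }
  if (!converged)
    warning("calibration did not converge within the evaluation budget; ",
            "returning best parameters found")
  par <- best$par
  # identifiability convention: the two sequential adenoma-compartment
  # rates are exchangeable (two-stage transit times are symmetric in
  # their rates), so report the labelling with
  # low_to_inthigh >= inthigh_to_crc
  if (par[["low_to_inthigh"]] < par[["inthigh_to_crc"]]) {
    tmp <- par[["low_to_inthigh"]]
    par[["low_to_inthigh"]] <- par[["inthigh_to_crc"]]
    par[["inthigh_to_crc"]] <- tmp
    dev_sw <- sum(resid_fn(par)^2)
    if (dev_sw > best$deviance + 1e-6 * (1 + best$deviance)) {
      # symmetry broken by strongly age-varying attrition: keep original
      par <- best$par
    } else best$deviance <- dev_sw
  }
  fitted <- vector_to_params(par, init)
  model <- build_transition_model(fitted, age_breaks = age_breaks,
                                  calibrated = TRUE)
  structure(list(fitted = fitted, model = model,
                 objective_value = best$deviance,
                 predicted = predicted_rates(model, pyramid, age_breaks),
                 converged = converged, evaluations = evals),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration %s: objective %.4g after %d evaluations\n",
              if (x$converged) "converged" else "DID NOT converge",
              x$objective_value, x$evaluations))
  print(x$fitted)
  invisible(x)
}

#' Read or write calibration targets
#'
#' Delimited table with columns `age_low`, `age_high`, `measure`
#' (`incidence`/`mortality`), `stage` (`I`-`IV`, empty for mortality),
#' `rate` (per 100,000 alive persons) and `weight`.
#'
#' @param path File path.
#' @param targets Targets data.frame.
#' @return `read_targets()` returns a `calibration_targets` data.frame.
#' @export
read_targets <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_low", "age_high", "measure", "stage", "rate", "weight")
  if (!all(need %in% names(d)))
    stop("targets file must have columns: ", paste(need, collapse = ", "))
  d$stage[d$stage %in% c("", "NA")] <- NA_character_
  if (any(d$rate < 0)) stop("target rates must be nonnegative")
  class(d) <- c("calibration_targets", "data.frame")
  d
}

#' @rdname read_targets
#' @export
write_targets <- function(targets, path) {
  utils::write.csv(targets, path, row.names = FALSE, na = "")
  invisible(path)
}
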