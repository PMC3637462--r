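#' Natural-history parameter set
#'
#' Annual transition probabilities governing the adenoma-carcinoma
#' sequence.  Adenoma onset is age-dependent on a log-linear scale;
#' all other rates are age-constant.  Other-cause mortality is a fixed
#' life-table-style input (per-year-of-age probabilities), not a fitted
#' quantity.
#'
#' @param onset_base Annual probability that normal epithelium develops a
#'   low-risk adenoma, at the reference age (55 years).
#' @param onset_slope Log-linear change in the onset probability per year
#'   of age: onset(a) = onset_base * exp(onset_slope * (a - 55)).
#' @param low_to_inthigh Annual probability a low-risk adenoma progresses
#'   to the intermediate/high-risk class (>=10 mm).
#' @param inthigh_to_crc Annual probability an intermediate/high-risk
#'   adenoma transforms to preclinical stage I CRC.
#' @param progression Length-3 vector: annual probability preclinical CRC
#'   advances stage I->II, II->III, III->IV.
#' @param presentation Length-4 vector: annual probability preclinical CRC
#'   of stage I..IV presents clinically (becomes diagnosed).
#' @param fatality Length-4 vector: annual CRC death probability while in
#'   clinical CRC stage I..IV.
#' @param remission Length-4 vector: annual probability a clinical CRC
#'   case of stage I..IV moves to long-term cancer care (after which CRC
#'   death risk is negligible).  Fixed input, not calibrated.
#' @param other_cause_mortality Numeric vector of annual death
#'   probabilities from causes other than CRC, one per year of age 30-99
#'   (names optional).  Defaults to a Gompertz schedule typical of a
#'   western European population.
#' @return An object of class `nh_params` (a named list).
#' @seealso [build_transition_model()], [calibrate_transitions()]
#' @export
nh_params <- function(onset_base = 0.008,
                      onset_slope = 0.04,
                      low_to_inthigh = 0.035,
                      inthigh_to_crc = 0.03,
                      progression = c(0.40, 0.45, 0.48),
                      presentation = c(0.10, 0.28, 0.50, 0.90),
                      fatality = c(0.01, 0.04, 0.15, 0.45),
                      remission = c(0.20, 0.15, 0.08, 0.02),
                      other_cause_mortality = gompertz_mortality()) {
  p <- list(onset_base = onset_base, onset_slope = onset_slope,
            low_to_inthigh = low_to_inthigh, inthigh_to_crc = inthigh_to_crc,
            progression = as.numeric(progression),
            presentation = as.numeric(presentation),
            fatality = as.numeric(fatality),
            remission = as.numeric(remission),
            other_cause_mortality = as.numeric(other_cause_mortality))
  class(p) <- "nh_params"
  validate_nh_params(p)
  p
}

#' @rdname nh_params
#' @param x Object to validate.
#' @export
validate_nh_params <- function(x) {
  stopifnot(inherits(x, "nh_params"))
  if (length(x$progression) != 3L)
    stop("'progression' must have 3 elements (I->II, II->III, III->IV)")
  if (length(x$presentation) != 4L || length(x$fatality) != 4L ||
      length(x$remission) != 4L)
    stop("'presentation', 'fatality' and 'remission' must have 4 elements")
  if (length(x$other_cause_mortality) != 70L)
    stop("'other_cause_mortality' must give one probability per age 30-99")
  probs <- c(x$onset_base, x$low_to_inthigh, x$inthigh_to_crc,
             x$progression, x$presentation, x$fatality, x$remission,
             x$other_cause_mortality)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all natural-history probabilities must lie in [0, 1]")
  invisible(x)
}

#' Gompertz schedule for other-cause mortality
#'
#' Annual probability of death from causes other than colorectal cancer,
#' q(a) = min(a_scale * exp(b_rate * age), cap), for ages 30-99.  The
#' defaults approximate an all-cause western European life table (about
#' 0.001 at age 35, 0.02 at 70, 0.12 at 90).
#'
#' @param a_scale,b_rate Gompertz level and rate parameters.
#' @param cap Upper bound on the annual probability.
#' @return Numeric vector of length 70, named by age.
#' @export
gompertz_mortality <- function(a_scale = 3e-05, b_rate = 0.092, cap = 0.7) {
  ages <- 30:99
  q <- pmin(a_scale * exp(b_rate * ages), cap)
  names(q) <- ages
  q
}

#' Adenoma onset probability at a given age
#'
#' @param params An [nh_params()] object.
#' @param age Age(s) in years.
#' @return Annual onset probability (capped at 1).
#' @export
adenoma_onset <- function(params, age) {
  pmin(params$onset_base * exp(params$onset_slope * (age - 55)), 1)
}

#' @export
print.nh_params <- function(x, ...) {
  cat("Natural-history parameter set\n")
  cat(sprintf("  adenoma onset: %.4f at age 55, log-slope %.3f/yr\n",
              x$onset_base, x$onset_slope))
  cat(sprintf("  low -> int/high adenoma: %.4f/yr\n", x$low_to_inthigh))
  cat(sprintf("  int/high adenoma -> preclinical CRC: %.4f/yr\n",
              x$inthigh_to_crc))
  cat(sprintf("  preclinical stage progression: %s\n",
              paste(sprintf("%.3f", x$progression), collapse = ", ")))
  cat(sprintf("  clinical presentation (I-IV): %s\n",
              paste(sprintf("%.3f", x$presentation), collapse = ", ")))
  cat(sprintf("  CRC case fatality (I-IV): %s\n",
              paste(sprintf("%.3f", x$fatality), collapse = ", ")))
  invisible(x)
}

# Names of the calibrated (free) parameters, in optimiser order.
.fitted_par_names <- c(
  "onset_base", "onset_slope", "low_to_inthigh", "inthigh_to_crc",
  "prog_I_II", "prog_II_III", "prog_III_IV",
  "pres_I", "pres_II", "pres_III", "pres_IV",
  "fatal_I", "fatal_II", "fatal_III", "fatal_IV")

# nh_params <-> flat named vector of the 15 calibrated parameters.
params_to_vector <- function(params) {
  v <- c(params$onset_base, params$onset_slope, params$low_to_inthigh,
         params$inthigh_to_crc, params$progression, params$presentation,
         params$fatality)
  names(v) <- .fitted_par_names
  v
}

vector_to_params <- function(v, template) {
  template$onset_base <- v[[1L]]
  template$onset_slope <- v[[2L]]
  template$low_to_inthigh <- v[[3L]]
  template$inthigh_to_crc <- v[[4L]]
  template$progression <- as.numeric(v[5:7])
  template$presentation <- as.numeric(v[8:11])
  template$fatality <- as.numeric(v[12:15])
  template
}

#' Read or write a natural-history parameter file
#'
#' Parameters are stored as structured text (YAML) with keys matching the
#' [nh_params()] arguments; `other_cause_mortality` is stored per year of
#' age.
#'
#' @param path File path.
#' @param params An [nh_params()] object.
#' @return `read_nh_params()` returns an [nh_params()] object;
#'   `write_nh_params()` returns `path` invisibly.
#' @export
read_nh_params <- function(path) {
  y <- yaml::read_yaml(path)
  nh_params(onset_base = y$onset_base, onset_slope = y$onset_slope,
            low_to_inthigh = y$low_to_inthigh,
            inthigh_to_crc = y$inthigh_to_crc,
            progression = unlist(y$progression),
            presentation = unlist(y$presentation),
            fatality = unlist(y$fatality),
            remission = unlist(y$remission),
            other_cause_mortality = unlist(y$other_cause_mortality))
}

#' @rdname read_nh_params
#' @export
write_nh_params <- function(params, path) {
  validate_nh_params(params)
  y <- unclass(params)
  y$other_cause_mortality <- as.list(stats::setNames(
    params$other_cause_mortality, as.character(30:99)))
  yaml::write_yaml(y, path, precision = 15L)
  invisible(path)
}
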