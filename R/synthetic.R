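#' Generate a synthetic population pyramid
#'
#' Builds a single-year-of-age population for ages 30-99 with a
#' configurable total and 55-74 share, emulating the age structure the
#' analyses are expressed against (a population of 4.4 million with
#' 700,800 aged 55-74).  The `bulge` shape declines log-linearly with
#' age, so cohorts below the screening ages are larger than those within
#' them and the screened population grows over the projection horizon,
#' as in a demographically young population; `flat` gives equal counts
#' within 55-74 (and within the remainder).  Counts inside and outside
#' the 55-74 block are scaled separately (largest-remainder rounding) so
#' the totals are met exactly.
#'
#' Generation is deterministic; `seed` is recorded for provenance and to
#' key downstream analyses.
#'
#' @param total_population Total persons in the reference population
#'   (all ages); the pyramid holds its ages-30-99 portion.
#' @param share_55_74 Fraction of `total_population` aged 55-74
#'   (0 < share < 1).
#' @param shape `"bulge"` (default) or `"flat"`.
#' @param seed Integer seed recorded on the pyramid.
#' @param bulge_slope Log-linear decline in cohort size per year of age
#'   for the bulge shape (the default 0.026 matches the roughly 1.3:1
#'   ratio of the 45-54 to the 55-64 age group in a demographically
#'   young western population, so the screening-age population grows
#'   over the projection decade).
#' @param ages_30_99_fraction Fraction of `total_population` aged 30-99
#'   (0.58 is typical of a demographically young western population).
#' @return A [population_pyramid()] with attribute `"seed"`.
#' @examples
#' p <- make_pyramid(4400000, 700800 / 4400000)
#' sum(p$counts[p$age >= 55 & p$age <= 74])  # 700,800
#' @export
make_pyramid <- function(total_population, share_55_74,
                         shape = c("bulge", "flat"), seed = 1L,
                         bulge_slope = 0.026, ages_30_99_fraction = 0.58) {
  shape <- match.arg(shape)
  if (share_55_74 <= 0 || share_55_74 >= ages_30_99_fraction)
    stop("'share_55_74' must lie in (0, ages_30_99_fraction)")
  if (total_population <= 0) stop("'total_population' must be positive")
  ages <- 30:99
  w <- if (shape == "flat") rep(1, 70L) else exp(-bulge_slope * (ages - 30))
  inside <- ages >= 55 & ages <= 74
  target_in <- round(total_population * share_55_74)
  target_out <- round(total_population * ages_30_99_fraction) - target_in
  if (target_out <= 0)
    stop("'ages_30_99_fraction' leaves no population outside ages 55-74")
  alloc <- function(weights, total) {
    x <- weights / sum(weights) * total
    f <- floor(x)
    rem <- total - sum(f)
    if (rem > 0) {
      ord <- order(x - f, decreasing = TRUE)
      f[ord[seq_len(rem)]] <- f[ord[seq_len(rem)]] + 1
    }
    f
  }
  counts <- numeric(70L)
  counts[inside] <- alloc(w[inside], target_in)
  counts[!inside] <- alloc(w[!inside], target_out)
  p <- population_pyramid(counts, reference_year = "synthetic")
  attr(p, "seed") <- as.integer(seed)
  p
}

#' Generate calibration targets from known parameters
#'
#' Produces age-band incidence (by stage) and CRC mortality targets equal
#' to the natural-history model's own cross-sectional rates at `truth`,
#' optionally perturbed by seeded multiplicative noise.  Calibration run
#' against noise-free targets should recover `truth` (parameter-recovery
#' testing).
#'
#' @param truth An [nh_params()] object (the generating parameters).
#' @param pyramid A [population_pyramid()].
#' @param age_breaks Band boundaries for target aggregation.
#' @param noise_sd Relative standard deviation of lognormal perturbation
#'   (0 = exact targets).
#' @param seed Integer seed for the perturbation.
#' @return A `calibration_targets` data.frame (see [read_targets()]):
#'   columns `age_low`, `age_high`, `measure` (`"incidence"` or
#'   `"mortality"`), `stage` (`I`-`IV`, `NA` for mortality), `rate` (per
#'   100,000 alive) and `weight`.
#' @export
make_targets <- function(truth, pyramid, age_breaks = seq(30, 100, by = 5),
                         noise_sd = 0, seed = 1L) {
  validate_nh_params(truth)
  model <- build_transition_model(truth, age_breaks = age_breaks)
  tg <- predicted_rates(model, pyramid, age_breaks)
  tg$weight <- 1
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    tg$rate <- tg$rate * exp(stats::rnorm(nrow(tg), 0, noise_sd))
  }
  class(tg) <- c("calibration_targets", "data.frame")
  tg
}

#' Base-case screening configuration
#'
#' The complete screening parameterisation: test profiles for gFOBT, FIT
#' and FSIG (with lower/upper sensitivity-analysis values as attributes),
#' the diagnostic work-up pathway, endoscopy harm rates, the
#' post-polypectomy surveillance rule, and resource-accounting constants.
#'
#' @param path Optional YAML file to read the configuration from (as
#'   written by [write_screening_config()]); the default returns the
#'   built-in base case.
#' @return A list of class `screening_config` with elements `tests`
#'   (list of [test_profile()]s), `sensitivity_bounds` (lower/upper
#'   values for uptake, sensitivity and specificity per test), `pathway`,
#'   `harms`, `rule`, `distal_fraction`, `weak_positive_fraction`,
#'   `adenomas_per_person` and `crc_workup_fractions`.
#' @export
base_case_config <- function(path = NULL) {
  if (!is.null(path)) return(read_screening_config(path))
  tests <- list(
    gFOBT = test_profile("gFOBT", sens_low_adenoma = 0.11,
                         sens_inthigh_adenoma = 0.11, sens_crc = 0.36,
                         specificity = 0.97, reach = "whole_colon",
                         uptake = 0.53),
    FIT = test_profile("FIT", sens_low_adenoma = 0.21,
                       sens_inthigh_adenoma = 0.21, sens_crc = 0.71,
                       specificity = 0.95, reach = "whole_colon",
                       uptake = 0.53),
    FSIG = test_profile("FSIG", sens_low_adenoma = 0.65,
                        sens_inthigh_adenoma = 0.74, sens_crc = 0.90,
                        specificity = 0.92, reach = "distal_only",
                        uptake = 0.39))
  bounds <- list(
    gFOBT = list(uptake = c(0.32, 0.70),
                 sens_adenoma = c(0.10, 0.12), sens_crc = c(0.31, 0.42),
                 specificity = c(0.96, 0.98)),
    FIT = list(uptake = c(0.32, 0.70),
               sens_adenoma = c(0.19, 0.22), sens_crc = c(0.67, 0.75),
               specificity = c(0.94, 0.96)),
    FSIG = list(uptake = c(0.24, 0.67),
                sens_low_adenoma = c(0.60, 0.70),
                sens_inthigh_adenoma = c(0.68, 0.78),
                sens_crc = c(0.85, 0.95), specificity = c(0.90, 0.95)))
  structure(list(tests = tests, sensitivity_bounds = bounds,
                 pathway = diagnostic_pathway(),
                 harms = harm_rates(),
                 rule = surveillance_rule(),
                 distal_fraction = 0.60,
                 weak_positive_fraction = 0,
                 adenomas_per_person = 1.9,
                 screen_detect_cure = screen_detect_cure(),
                 crc_workup_fractions = crc_workup_fractions()),
            class = "screening_config")
}

#' The bundled toy-Ireland test instance
#'
#' A small, fully synthetic stand-in for the study population: the
#' synthetic pyramid (4.4 million aged 30-99, 700,800 aged 55-74, bulge
#' shape), the default natural-history parameters treated as calibrated
#' truth, and the base-case screening configuration.  It is the
#' canonical instance used by the test-suite and worked examples.
#'
#' @return List with `pyramid`, `params`, `model` (a calibrated
#'   `transition_model`) and `config`.
#' @export
toy_ireland <- function() {
  params <- nh_params()
  list(pyramid = make_pyramid(4400000, 700800 / 4400000),
       params = params,
       model = build_transition_model(params),
       config = base_case_config())
}

#' Read or write a screening configuration file
#'
#' Structured text (YAML) with keys mirroring the parameter-table names.
#'
#' @param path File path.
#' @param config A `screening_config` (see [base_case_config()]).
#' @return `read_screening_config()` returns a `screening_config`.
#' @export
write_screening_config <- function(config, path) {
  y <- list(
    tests = lapply(config$tests, function(t) unclass(t)),
    sensitivity_bounds = config$sensitivity_bounds,
    pathway = unclass(config$pathway),
    harms = unclass(config$harms),
    surveillance = unclass(config$rule),
    distal_fraction = config$distal_fraction,
    weak_positive_fraction = config$weak_positive_fraction,
    adenomas_per_person = config$adenomas_per_person,
    screen_detect_cure = as.list(config$screen_detect_cure),
    crc_workup_fractions = config$crc_workup_fractions)
  yaml::write_yaml(y, path, precision = 15L)
  invisible(path)
}

#' @rdname write_screening_config
#' @export
read_screening_config <- function(path) {
  y <- yaml::read_yaml(path)
  tests <- lapply(y$tests, function(t)
    test_profile(t$name, t$sens_low_adenoma, t$sens_inthigh_adenoma,
                 t$sens_crc, t$specificity, t$reach, t$uptake))
  pw <- do.call(diagnostic_pathway, y$pathway)
  hm <- do.call(harm_rates, y$harms)
  rl <- do.call(surveillance_rule, y$surveillance)
  structure(list(tests = tests, sensitivity_bounds = y$sensitivity_bounds,
                 pathway = pw, harms = hm, rule = rl,
                 distal_fraction = y$distal_fraction,
                 weak_positive_fraction = y$weak_positive_fraction,
                 adenomas_per_person = y$adenomas_per_person,
                 screen_detect_cure = do.call(screen_detect_cure,
                                              y$screen_detect_cure),
                 crc_workup_fractions = y$crc_workup_fractions),
            class = "screening_config")
}
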