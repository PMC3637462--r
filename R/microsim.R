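#' Individual-level microsimulation of the natural history
#'
#' Simulates `n` individuals from age 30 through the natural-history
#' chain by sampling one transition per person per cycle from the same
#' age-banded matrices used by the cohort model.  Used as an independent
#' stochastic oracle: cohort-model state occupancies are expectations of
#' the microsimulation, so observed occupancy fractions should agree
#' within binomial sampling error.
#'
#' @param model A `transition_model`.
#' @param n Number of simulated individuals.
#' @param years Number of one-year cycles from age 30.
#' @param seed Integer seed (simulation is reproducible given the seed).
#' @return List with `occupancy` (years+1 x 16 matrix of person counts;
#'   row y is the state at age 29+y before any transition),
#'   `final_counts` (named counts at the horizon) and `n`.
#' @export
microsimulate <- function(model, n = 1e5, years = 40, seed = 1L) {
  stopifnot(inherits(model, "transition_model"), n >= 1, years >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- health_states()
  state <- rep(1L, n)                       # everyone starts Normal at 30
  occ <- matrix(0L, years + 1L, 16L, dimnames = list(NULL, s))
  occ[1L, ] <- tabulate(state, 16L)
  age <- 30
  for (y in seq_len(years)) {
    if (age >= 100) {
      alive <- !(state %in% c(15L, 16L))
      state[alive] <- 16L
    } else {
      b <- band_index(model, age)
      Mcum <- t(apply(model$matrices[[b]], 1L, cumsum))
      u <- stats::runif(n)
      new_state <- state
      for (si in unique(state)) {
        idx <- which(state == si)
        new_state[idx] <- findInterval(u[idx], Mcum[si, ],
                                       rightmost.closed = FALSE) + 1L
      }
      state <- new_state
    }
    occ[y + 1L, ] <- tabulate(state, 16L)
    age <- age + 1
  }
  list(occupancy = occ,
       final_counts = stats::setNames(occ[years + 1L, ], s), n = n)
}
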