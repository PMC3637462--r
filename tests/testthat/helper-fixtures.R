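# Shared fixtures, built once per test run.

toy <- toy_ireland()

# A small natural-history chain with hand-chosen rates and no competing
# mortality: used wherever expected values are derived by hand.
toy_chain_params <- function(onset = 0.1, l2h = 0.2, h2c = 0.3,
                             prog = c(0.15, 0.15, 0.15),
                             pres = c(0.25, 0.3, 0.4, 0.9),
                             fatal = c(0.05, 0.1, 0.2, 0.4),
                             q_other = 0) {
  nh_params(onset_base = onset, onset_slope = 0,
            low_to_inthigh = l2h, inthigh_to_crc = h2c,
            progression = prog, presentation = pres, fatality = fatal,
            remission = c(0, 0, 0, 0),
            other_cause_mortality = rep(q_other, 70))
}

# A pyramid with all mass in a single age (defaults to a cohort of
# thirty-year-olds), for single-cohort traces.
single_age_pyramid <- function(age = 30, n = 1000) {
  counts <- numeric(70)
  counts[age - 29] <- n
  population_pyramid(counts)
}

expect_all_finite <- function(x) expect_true(all(is.finite(unlist(x))))
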