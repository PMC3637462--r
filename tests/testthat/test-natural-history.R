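test_that("transition model satisfies its structural invariants", {
  m <- build_transition_model(nh_params())
  expect_s3_class(m, "transition_model")
  expect_equal(nrow(m$age_bands), 14L)
  for (M in m$matrices) {
    expect_true(all(M >= 0 & M <= 1))
    expect_lt(max(abs(rowSums(M) - 1)), 1e-12)
    for (a in absorbing_states())
      expect_identical(unname(M[a, ]),
                       as.numeric(health_states() == a))
  }
  # other-cause death is age-increasing across bands
  q <- vapply(m$matrices, function(M) M["Normal", "OtherDeath"], numeric(1))
  expect_true(all(diff(q) >= 0))
})

test_that("degenerate chain with mortality only leaves disease states alone", {
  p <- nh_params(onset_base = 0, onset_slope = 0, low_to_inthigh = 0,
                 inthigh_to_crc = 0, progression = c(0, 0, 0),
                 presentation = c(0, 0, 0, 0), fatality = c(0, 0, 0, 0),
                 remission = c(0, 0, 0, 0))
  m <- build_transition_model(p)
  for (M in m$matrices) {
    alive <- setdiff(health_states(), absorbing_states())
    for (s in alive) {
      off <- M[s, setdiff(health_states(), c(s, "OtherDeath"))]
      expect_true(all(off == 0))
    }
  }
})

test_that("matrix rows match direct construction on a toy chain", {
  p <- toy_chain_params()
  m <- build_transition_model(p)
  M <- m$matrices[[1]]
  expect_equal(unname(M["Normal", c("Normal", "AdenomaLowRisk")]),
               c(0.9, 0.1))
  expect_equal(unname(M["AdenomaLowRisk",
                        c("AdenomaLowRisk", "AdenomaIntHighRisk")]),
               c(0.8, 0.2))
  expect_equal(unname(M["PreclinicalCRC_I",
                        c("PreclinicalCRC_I", "PreclinicalCRC_II",
                          "ClinicalCRC_I")]),
               c(1 - 0.15 - 0.25, 0.15, 0.25))
})

test_that("invalid rows are reported with state and age band", {
  m <- build_transition_model(nh_params())
  m$matrices[[3]]["AdenomaLowRisk", "Normal"] <- 0.5
  expect_error(validate_transition_model(m), "AdenomaLowRisk")
  expect_error(validate_transition_model(m), "40-44")
})

test_that("step_cohort multiplies by the age-appropriate matrix", {
  p <- toy_chain_params()
  m <- build_transition_model(p)
  d0 <- c(0.5, 0.2, 0.1, 0.05, 0, 0, 0, 0.05, 0, 0, 0, 0, 0, 0, 0, 0.1)
  co <- cohort_state(40, 100, d0)
  # two steps equal the hand-computed two-fold matrix product
  M <- m$matrices[[3]]  # band 40-44
  expected <- as.numeric((d0 %*% M) %*% M)
  co2 <- step_cohort(step_cohort(co, m), m)
  expect_equal(unname(co2$distribution), expected, tolerance = 1e-14)
  expect_equal(co2$age, 42)
  expect_equal(sum(co2$distribution), 1, tolerance = 1e-12)
})

test_that("identity dynamics leave the distribution unchanged", {
  p <- toy_chain_params(onset = 0, l2h = 0, h2c = 0, prog = c(0, 0, 0),
                        pres = c(0, 0, 0, 0), fatal = c(0, 0, 0, 0))
  m <- build_transition_model(p)
  d0 <- c(0.7, 0.1, 0.1, 0, 0, 0, 0, 0.1, 0, 0, 0, 0, 0, 0, 0, 0)
  co <- step_cohort(cohort_state(50, 10, d0), m)
  expect_equal(unname(co$distribution), d0)
  expect_equal(co$age, 51)
})

test_that("absorbing mass stays absorbed forever", {
  m <- build_transition_model(nh_params())
  d0 <- c(rep(0, 15), 1)
  co <- cohort_state(60, 1, d0)
  for (i in 1:5) co <- step_cohort(co, m)
  expect_equal(unname(co$distribution), d0)
})

test_that("cohorts exit the model at age 100", {
  m <- build_transition_model(nh_params())
  co <- cohort_state(99, 10)
  co <- step_cohort(co, m)          # -> 100
  co <- step_cohort(co, m)          # exits: all alive mass absorbed
  expect_equal(alive_fraction(co), 0)
  expect_equal(sum(co$distribution), 1)
  expect_equal(co$age, 101)
})

test_that("trace incidence matches path enumeration on the toy chain", {
  o <- 0.1; a <- 0.2; b <- 0.3; p1 <- 0.15; c1 <- 0.25
  p <- toy_chain_params(onset = o, l2h = a, h2c = b)
  m <- build_transition_model(p)
  tr <- natural_history_trace(single_age_pyramid(30, 1000), m, 5)
  # the earliest path Normal -> Low -> IntHigh -> Preclinical I ->
  # Clinical I takes four cycles with no dwell anywhere:
  inc4 <- 1000 * o * a * b * c1
  # year five adds one extra dwell year in exactly one compartment:
  inc5 <- 1000 * o * a * b * c1 *
    ((1 - o) + (1 - a) + (1 - b) + (1 - p1 - c1))
  expect_equal(tr$incidence_I[1:3], c(0, 0, 0))
  expect_equal(tr$incidence_I[4], inc4, tolerance = 1e-12)
  expect_equal(tr$incidence_I[5], inc5, tolerance = 1e-12)
  expect_equal(tr$incidence_total[4], inc4, tolerance = 1e-12)
})

test_that("zero progression gives zero incidence and CRC mortality", {
  p <- toy_chain_params(onset = 0, l2h = 0, h2c = 0, q_other = 0.01)
  m <- build_transition_model(p)
  tr <- natural_history_trace(toy$pyramid, m, 3)
  expect_equal(tr$incidence_total, rep(0, 3))
  expect_equal(tr$crc_deaths, rep(0, 3))
})

test_that("trace counts are homogeneous of degree one in cohort size", {
  m <- toy$model
  p1 <- toy$pyramid
  p2 <- population_pyramid(p1$counts * 2)
  t1 <- natural_history_trace(p1, m, 3)
  t2 <- natural_history_trace(p2, m, 3)
  expect_equal(t2$incidence_total, 2 * t1$incidence_total)
  expect_equal(t2$crc_deaths, 2 * t1$crc_deaths)
  expect_equal(t2$incidence_total_rate, t1$incidence_total_rate,
               tolerance = 1e-12)
})

test_that("empty pyramid is rejected", {
  expect_error(population_pyramid(rep(0, 70)), "positive")
})

test_that("mass is conserved and death mass is monotone over a lifetime", {
  m <- toy$model
  co <- cohort_state(30, 1)
  dead_prev <- 0
  for (i in 1:70) {
    co <- step_cohort(co, m)
    expect_lt(abs(sum(co$distribution) - 1), 1e-9)
    dead <- sum(co$distribution[absorbing_states()])
    expect_gte(dead, dead_prev - 1e-12)
    dead_prev <- dead
  }
})

test_that("transition matrices round-trip through the long serialization", {
  m <- toy$model
  path <- withr::local_tempfile(fileext = ".csv")
  write_transition_matrices(m, path)
  long <- read_transition_matrices(path)
  expect_setequal(names(long), c("age_low", "age_high", "from", "to", "prob"))
  for (b in c(1, 7, 14)) {
    lo <- m$age_bands$lower[b]
    sub <- long[long$age_low == lo, ]
    M <- m$matrices[[b]]
    expect_equal(nrow(sub), sum(M != 0))
    expect_equal(sub$prob[sub$from == "Normal" & sub$to == "AdenomaLowRisk"],
                 M["Normal", "AdenomaLowRisk"])
  }
})
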