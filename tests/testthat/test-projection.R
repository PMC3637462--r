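test_that("invitation schedules match the programme definitions", {
  base <- scenario_spec("FIT")
  slow <- scenario_spec("FIT", rollout = "slow")
  med <- scenario_spec("FIT", rollout = "medium")
  restr <- scenario_spec("FIT", rollout = "age_restricted")
  none <- scenario_spec("none")
  fsig <- scenario_spec("FSIG")

  expect_equal(invited_ages(slow, 1), 55L)
  expect_equal(invited_ages(slow, 2), c(55L, 57L))
  expect_equal(invited_ages(med, 1), c(55L, 65L))
  expect_equal(invited_ages(med, 2), c(55L, 57L, 65L, 67L))
  expect_equal(invited_ages(med, 3), c(55L, 57L, 59L, 65L, 67L, 69L))
  expect_equal(invited_ages(base, 1), seq(55L, 73L, by = 2L))
  expect_equal(invited_ages(restr, 4), seq(55L, 63L, by = 2L))
  expect_equal(invited_ages(fsig, 7), 60L)
  for (y in 1:10) expect_length(invited_ages(none, y), 0L)
  expect_true(invitation_schedule(base, 1, 61))
  expect_false(invitation_schedule(base, 1, 62))
})

test_that("roll-out schedules nest: slow within medium within base", {
  slow <- scenario_spec("FIT", rollout = "slow")
  med <- scenario_spec("FIT", rollout = "medium")
  base <- scenario_spec("FIT")
  for (y in 1:10) {
    expect_true(all(invited_ages(slow, y) %in% invited_ages(med, y)))
    expect_true(all(invited_ages(med, y) %in% invited_ages(base, y)))
  }
  # both reach the full invited set: medium by year 5, slow by year 10
  expect_equal(invited_ages(med, 5), invited_ages(base, 5))
  expect_equal(invited_ages(slow, 10), invited_ages(base, 10))
})

test_that("no-screening projection reduces to the pure natural history", {
  led <- run_scenario(toy$pyramid, toy$model, scenario_spec("none"),
                      toy$config)
  tr <- natural_history_trace(toy$pyramid, toy$model, 10)
  expect_identical(led$ledger$crc_cases, tr$incidence_total)
  expect_identical(led$ledger$crc_deaths, tr$crc_deaths)
  expect_identical(led$ledger$alive, tr$alive)
  screening_fields <- c("kits_sent", "kits_processed", "fsig_done",
                        "diagnostic_col", "diagnostic_ctc",
                        "surveillance_col", "surveillance_ctc",
                        "pathology_lesions", "pet", "resections",
                        "bleeds", "perforations", "perf_deaths",
                        "adenoma_persons_total", "crc_total")
  expect_true(all(as.matrix(led$ledger[, screening_fields]) == 0))
})

test_that("an uncalibrated sentinel model is refused", {
  m <- build_transition_model(toy$params, calibrated = FALSE)
  expect_error(run_scenario(toy$pyramid, m, scenario_spec("FIT"),
                            toy$config), "calibrat")
})

test_that("year one has no surveillance procedures in any scenario", {
  for (s in c("FIT", "gFOBT_reflex_FIT", "FSIG")) {
    led <- run_scenario(toy$pyramid, toy$model, scenario_spec(s),
                        toy$config)
    expect_equal(led$ledger$surveillance_col[1], 0)
    expect_equal(led$ledger$surveillance_ctc[1], 0)
    expect_gt(led$ledger$surveillance_col[10], 0)
  }
})

test_that("summing over cohorts then years matches years then cohorts", {
  led <- run_scenario(toy$pyramid, toy$model, scenario_spec("FIT"),
                      toy$config, by_cohort = TRUE)
  by_cohort_totals <- apply(led$by_cohort, c(1, 2), sum)
  fields <- colnames(by_cohort_totals)
  expect_equal(by_cohort_totals,
               as.matrix(led$ledger[, fields]),
               tolerance = 1e-9, ignore_attr = TRUE)
  # grand totals agree whichever axis is collapsed first
  expect_equal(sum(apply(led$by_cohort[, "diagnostic_col", ], 2, sum)),
               sum(led$ledger$diagnostic_col), tolerance = 1e-9)
})

test_that("FSIG exposures never exceed the population passing the screening age", {
  led <- run_scenario(toy$pyramid, toy$model, scenario_spec("FSIG"),
                      toy$config)
  # only cohorts aged 51-60 at baseline reach age 60 within ten years
  ever_eligible <- sum(toy$pyramid$counts[toy$pyramid$age %in% 51:60])
  expect_lte(sum(led$ledger$fsig_done), ever_eligible)
  expect_true(all(led$ledger$kits_sent == 0))
})

test_that("age-restricted screening uses no more resources than the full range", {
  full <- run_scenario(toy$pyramid, toy$model, scenario_spec("FIT"),
                       toy$config)
  restr <- run_scenario(toy$pyramid, toy$model,
                        scenario_spec("FIT", rollout = "age_restricted"),
                        toy$config)
  for (f in c("kits_sent", "kits_processed", "diagnostic_col",
              "diagnostic_ctc", "surveillance_col", "pathology_lesions",
              "crc_total", "perforations"))
    expect_true(all(restr$ledger[[f]] <= full$ledger[[f]] + 1e-9))
})

test_that("later rounds see lower cancer prevalence in the screened pool", {
  led <- run_scenario(toy$pyramid, toy$model, scenario_spec("FIT"),
                      toy$config)
  # detected cancers per screened person fall between rounds one and ten
  yield1 <- led$ledger$crc_total[1] / led$ledger$kits_processed[1]
  yield10 <- led$ledger$crc_total[10] / led$ledger$kits_processed[10]
  expect_lt(yield10, yield1)
})

test_that("CRC work-up accounting multiplies detections by fixed fractions", {
  expect_equal(unname(account_crc_workup(c(0, 0, 0, 0))), rep(0, 6))
  f1 <- crc_workup_fractions(1, 1, 1, 1, 1, 1)
  expect_equal(unname(account_crc_workup(c(10, 20, 5, 5), f1)),
               rep(40, 6))
  # year-one counts for 309 detected cancers, within rounding of the
  # published resource table
  wk <- round_half_out(account_crc_workup(c(111, 105, 69, 24)))
  expect_equal(unname(wk[c("pet", "mri", "ct", "tus", "preop_rt",
                           "resections")]),
               c(31, 111, 309, 16, 71, 281))
  expect_error(account_crc_workup(c(1, 1, 1, 1), list(pet = 2)), "fraction")
})

test_that("reports apply half-away-from-zero rounding and the pathology identity", {
  expect_equal(round_half_out(c(0.5, 1.5, -0.5, 2.4, -2.5)),
               c(1, 2, -1, 2, -3))
  led <- run_scenario(toy$pyramid, toy$model, scenario_spec("FIT"),
                      toy$config)
  rep <- report_ledger(led)
  stopifnot(!anyNA(rep))
  adeno <- unlist(rep[rep$field == "adenoma_persons_total", -1])
  crc <- unlist(rep[rep$field == "crc_total", -1])
  path <- unlist(rep[rep$field == "pathology_lesions", -1])
  expect_equal(path, round_half_out(adeno * 1.9) + crc)
  # ledger report round-trips through the delimited layout
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ledger_report(led, f, header = c("seed: 1"))
  back <- read_ledger_report(f)
  expect_equal(back$year_1, rep$year_1)
  expect_equal(back$field, rep$field)
})
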