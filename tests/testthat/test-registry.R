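test_that("eligibility boundaries are exact and inclusive", {
  # 5 months since diagnosis -> too early even with low EDSS
  p <- reference_patient()
  early <- check_eligibility(p, add_months(p$diagnosis_date, 5))
  expect_false(early$eligible)
  expect_match(early$reason, "6 months")

  # EDSS above 6 at an otherwise valid switch
  p65 <- reference_patient(edss_score = 6.5)
  high <- check_eligibility(p65, as.Date("2015-06-01"))
  expect_false(high$eligible)
  expect_match(high$reason, "EDSS > 6")

  # both boundary values accepted: exactly 6 months, exactly EDSS 6.0
  p6 <- patient_record(
    patient_id = "b", sex = "male", birth_year = 1985,
    diagnosis_date = as.Date("2015-01-01"),
    episodes = data.frame(dmt_id = "interferon_beta",
                          start_date = as.Date("2015-01-15"),
                          end_date = as.Date("2016-06-01")),
    edss = data.frame(date = as.Date("2015-06-01"), score = 6.0)
  )
  boundary_date <- add_months(as.Date("2015-01-01"), 6)
  expect_true(check_eligibility(p6, boundary_date)$eligible)
  expect_false(check_eligibility(p6, boundary_date - 2)$eligible)

  # no EDSS on record before index
  none <- check_eligibility(reference_patient(), as.Date("2015-01-01"))
  expect_false(none$eligible)
  expect_match(none$reason, "no EDSS")
})

test_that("predictor extraction matches hand-computed values and is pure", {
  p <- reference_patient()
  idx <- as.Date("2015-06-01")
  x <- extract_predictors(p, idx)

  # relapses at index-100d and index-400d: one inside the 12-month window
  expect_identical(x$relapses_last_12m, 1L)
  expect_equal(x$time_since_last_relapse, 100 / 30.4375, tolerance = 1e-10)
  # current therapy is the one being discontinued at the switch
  expect_identical(x$current_dmt, "interferon_beta")
  expect_equal(x$current_dmt_duration, months_between(as.Date("2012-01-01"), idx))
  # no previous therapy before the interferon episode
  expect_identical(x$n_previous_dmts, 0L)
  expect_false(x$any_previous_second_line)
  expect_equal(x$edss, 2.0)
  expect_equal(x$time_since_diagnosis, months_between(as.Date("2010-01-01"), idx))

  # one DMT later: now natalizumab is current, interferon is the single
  # previous therapy, and it is first-line
  x2 <- extract_predictors(p, as.Date("2016-06-01"))
  expect_identical(x2$current_dmt, "natalizumab")
  expect_identical(x2$n_previous_dmts, 1L)
  expect_false(x2$any_previous_second_line)

  # purity: identical inputs give identical vectors
  expect_identical(x, extract_predictors(p, idx))

  # never-relapsed patient gets the cap
  p0 <- reference_patient()
  p0$relapses <- as.Date(character())
  x0 <- extract_predictors(p0, idx)
  expect_identical(x0$relapses_last_12m, 0L)
  expect_equal(x0$time_since_last_relapse, 120)

  # no episode covering the index date
  expect_error(extract_predictors(p, as.Date("2011-01-01")), "no current DMT")
})

test_that("3-month confirmed progression follows the step-and-confirm rule", {
  mk <- function(scores, offsets_months) {
    p <- reference_patient()
    idx <- as.Date("2015-06-01")
    p$edss <- data.frame(
      date = c(idx - 10, add_months(idx, offsets_months)),
      score = c(2.0, scores)
    )
    p
  }
  idx <- as.Date("2015-06-01")

  # increase to 3.0 confirmed 3 months later
  r <- derive_3mcdp(mk(c(3.0, 3.0), c(2, 5)), idx)
  expect_true(r$event)
  expect_false(r$censored)
  expect_equal(r$event_date, add_months(idx, 2))

  # increase that regresses before confirmation
  r2 <- derive_3mcdp(mk(c(3.0, 2.0), c(2, 5)), idx)
  expect_false(r2$event)
  expect_false(r2$censored)

  # no follow-up assessments at all
  p3 <- reference_patient()
  p3$edss <- data.frame(date = idx - 10, score = 2.0)
  r3 <- derive_3mcdp(p3, idx)
  expect_false(r3$event)
  expect_true(r3$censored)

  # reference above 5.5 needs only a 0.5-point step
  p4 <- mk(c(6.5, 6.5), c(2, 5))
  p4$edss$score[1] <- 6.0
  expect_true(derive_3mcdp(p4, idx)$event)

  # a 1.0-point step is required at reference 2.0: +0.5 is not an event
  expect_false(derive_3mcdp(mk(c(2.5, 2.5), c(2, 5)), idx)$event)
})

test_that("3mCDP is monotone in the horizon", {
  spec <- generator_spec(n_patients = 30, seed = 99)
  cohort <- generate_cohort(spec)
  horizons <- c(6, 12, 24, 48, 60)
  for (p in cohort) {
    idx <- p$episodes$start_date[nrow(p$episodes)]
    if (is.null(last_ed <- dmtrank:::last_edss_before(p, idx))) next
    ev <- vapply(horizons, function(h) derive_3mcdp(p, idx, h)$event, TRUE)
    # once an event, always an event at longer horizons
    expect_true(all(diff(as.integer(ev)) >= 0))
  }
})

test_that("switch-table construction filters ineligible switches, never aborts", {
  ok <- reference_patient()
  early <- reference_patient()
  early$diagnosis_date <- as.Date("2015-05-01")   # < 6 months at the switch
  high <- reference_patient(edss_score = 7.0)     # EDSS > 6 at the switch
  high$patient_id <- "high"
  early$patient_id <- "early"

  tab <- build_switch_table(list(ok, early, high))
  expect_s3_class(tab, "switch_table")
  # ok contributes 2 switches (into natalizumab; second has no later data ->
  # but exposure>0 since episodes closed); early/high contribute none at the
  # first switch; their later natalizumab switch is still screened on its
  # own merits
  expect_true(all(tab$patient_id != "early") || all(
    months_between(early$diagnosis_date, tab$index_date[tab$patient_id == "early"]) >= 6))
  expect_true(!"high" %in% tab$patient_id ||
                all(tab$edss[tab$patient_id == "high"] <= 6))
  expect_true(all(tab$exposure_months > 0))

  # empty cohort -> empty table with full schema
  empty <- build_switch_table(list())
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("patient_id", "assigned_dmt", "relapse_count",
                    "cdp_event") %in% names(empty)))
})

test_that("switch-table row count equals a hand count on a 10-patient cohort", {
  # seven eligible one-switch patients, one diagnosed too recently, one with
  # EDSS 7, one with no EDSS before the switch
  mk_ok <- function(id) {
    p <- reference_patient()
    p$patient_id <- id
    p
  }
  cohort <- lapply(sprintf("ok%d", 1:7), mk_ok)
  late <- reference_patient()
  late$patient_id <- "late"
  late$diagnosis_date <- as.Date("2015-04-01")
  noedss <- reference_patient()
  noedss$patient_id <- "noedss"
  noedss$edss <- data.frame(date = as.Date("2016-01-01"), score = 2.0)
  cohort <- c(cohort, list(late, reference_patient(edss_score = 7.0), noedss))
  cohort[[9]]$patient_id <- "high"

  tab <- build_switch_table(cohort)
  expect_identical(nrow(tab), 7L)
  expect_setequal(unique(tab$patient_id), sprintf("ok%d", 1:7))
  expect_identical(sum(attr(tab, "skipped")), 3L)
})
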