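test_that("adherence labels agree with the patient-level ranking", {
  tab <- fixture_table()[1:20, ]
  fit <- fixture_fit("relapse")
  P <- ranking_matrix(fit, tab, horizon_months = 48)
  top1 <- label_adherence(tab, fit, "top1")
  top2 <- label_adherence(tab, fit, "top2")
  bottom2 <- label_adherence(tab, fit, "bottom2")
  for (i in seq_len(nrow(tab))) {
    o <- colnames(P)[order(-P[i, ])]
    rk <- match(tab$assigned_dmt[i], o)
    expect_identical(top1[i], rk == 1)
    expect_identical(top2[i], rk <= 2)
    expect_identical(bottom2[i], rk >= ncol(P) - 1)
  }
  # scenario consistency: top1 followers are top2 followers; bottom2 is
  # disjoint from top2 with an 8-therapy catalogue
  expect_true(all(top2[top1]))
  expect_false(any(top2 & bottom2))
})

test_that("propensity weighting balances a confounded adherence label", {
  tab <- generate_adherence_table(n = 700, seed = 9,
                                  base_table = fixture_table())
  pw <- propensity_weights(tab, tab$followed)
  expect_gt(max(abs(pw$balance$smd_unweighted)), 0.25)
  expect_lt(max(abs(pw$balance$smd_weighted)), 0.1)
  # stabilised weights average one in each group before trimming
  expect_equal(mean(pw$weights_untrimmed[tab$followed]), 1, tolerance = 1e-6)
  expect_equal(mean(pw$weights_untrimmed[!tab$followed]), 1, tolerance = 1e-6)
  expect_true(all(pw$weights > 0))

  # labels independent of covariates: nothing to correct
  rand <- with_seed_test(2, sample(tab$followed))
  pw0 <- propensity_weights(tab, rand)
  expect_lt(max(abs(pw0$balance$smd_weighted)), 0.15)
  expect_lt(stats::sd(pw0$weights), 0.2)

  expect_error(propensity_weights(tab, rep(TRUE, nrow(tab))), "non-empty")

  # matching variant returns 0/1 weights with equal group sizes
  pm <- propensity_weights(tab, tab$followed, method = "matching")
  expect_true(all(pm$weights %in% c(0, 1)))
  expect_identical(sum(pm$weights[tab$followed]),
                   sum(pm$weights[!tab$followed]))
})

test_that("the survey-weighted outcome models recover a known adherence effect", {
  base <- build_switch_table(generate_cohort(
    generator_spec(n_patients = 2500, seed = 33)))
  tab <- generate_adherence_table(n = nrow(base), delta_log_rr = -0.51,
                                  delta_log_or = -0.45, seed = 10,
                                  base_table = base)
  pw <- propensity_weights(tab, tab$followed)
  rel <- weighted_outcome_model(tab, pw$weights, tab$followed, "relapse")
  expect_lt(abs(rel$slope - (-0.51)), 0.15)
  expect_lt(rel$p_value, 0.01)
  expect_identical(rel$n_followed + rel$n_other, nrow(tab))
  cdp <- weighted_outcome_model(tab, pw$weights, tab$followed, "cdp")
  expect_lt(cdp$slope, 0)
  expect_lt(cdp$p_value, 0.05)
  expect_output(print(rel), "slope")

  # degenerate outcome: flagged, no estimate
  zero <- tab
  zero$relapse_count <- 0L
  res0 <- weighted_outcome_model(zero, pw$weights, tab$followed, "relapse")
  expect_true(is.na(res0$slope))
  expect_match(res0$flag, "degenerate")
  expect_error(weighted_outcome_model(tab, rep(-1, nrow(tab)), tab$followed),
               "finite and non-negative")
})

test_that("the scenario grid recovers the expected sign pattern when the ranking is informative", {
  tab <- build_switch_table(generate_cohort(
    generator_spec(n_patients = 2200, seed = 61)))
  fr <- suppressWarnings(fit_outcome_model(tab, fast_spec("relapse", seed = 3)))
  fc <- suppressWarnings(fit_outcome_model(tab, fast_spec("cdp", seed = 3)))
  grid <- run_scenarios(tab, fr, fc)
  expect_identical(nrow(grid), 6L)
  expect_identical(grid$n_followed + grid$n_other, rep(nrow(tab), 6L))
  # ranking-driven adherence is strongly confounded; weighting must improve
  # balance even where trimming leaves residual imbalance
  expect_true(all(grid$max_smd_weighted < grid$max_smd_unweighted))
  top <- grid[grid$scenario %in% c("top1", "top2"), ]
  bottom <- grid[grid$scenario == "bottom2", ]
  expect_true(all(top$slope < 0))
  expect_true(all(bottom$slope > 0))
  # group outcome summaries point the same way as the slopes
  expect_true(all(top$outcome_followed < top$outcome_other))
  expect_true(all(bottom$outcome_followed > bottom$outcome_other))
})

test_that("trial-arm comparison filters, predicts and flags discrepancies", {
  tab <- fixture_table()
  fit <- fixture_fit("relapse")
  arm <- rct_arm_spec("SYNTH-1", "natalizumab", "relapse",
                      duration_months = 24, published_event_free = 0.7,
                      filters = list(edss_max = 4, age_min = 18,
                                     min_relapses_12m = 1))
  cmp <- compare_with_rct(tab, fit, arm)
  manual_n <- sum(tab$edss <= 4 & tab$age >= 18 & tab$relapses_last_12m >= 1)
  expect_identical(cmp$n, manual_n)
  expect_true(cmp$predicted > 0 && cmp$predicted < 1)
  expect_true(cmp$ci90[1] <= cmp$predicted && cmp$predicted <= cmp$ci90[2])
  expect_identical(cmp$flagged, abs(cmp$difference) >= 0.10)
  expect_true(all(c("age", "edss") %in% cmp$baseline$covariate))
  expect_output(print(cmp), "SYNTH-1")

  # zero trial duration: everyone is event-free
  arm0 <- rct_arm_spec("SYNTH-0", "natalizumab", "relapse",
                       duration_months = 0, published_event_free = 0.99)
  expect_equal(compare_with_rct(tab, fit, arm0)$predicted, 1)

  # a filter that excludes everyone names itself
  armx <- rct_arm_spec("SYNTH-X", "natalizumab", "relapse",
                       duration_months = 24, published_event_free = 0.7,
                       filters = list(edss_min = 9.5))
  expect_error(compare_with_rct(tab, fit, armx), "edss_min")
  expect_error(rct_arm_spec("T", "x", "relapse", 24, 0.7,
                            filters = list(bogus = 1)), "unknown filter")
})

test_that("arm specifications load from JSON", {
  arms <- read_rct_arms(system.file("extdata", "rct_arms_synthetic.json",
                                    package = "dmtrank"))
  expect_gte(length(arms), 2L)
  expect_s3_class(arms[[1]], "rct_arm_spec")
  expect_true(all(vapply(arms, function(a) a$published_event_free, 0) > 0))
})
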