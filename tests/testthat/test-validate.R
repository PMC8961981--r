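test_that("concordance index handles the canonical cases", {
  expect_identical(c_index(1:10, 1:10), 1)
  expect_identical(c_index(10:1, 1:10), 0)
  # prediction ties count half
  expect_equal(c_index(c(1, 1), c(0, 1)), 0.5)
  # all outcomes identical -> flagged undefined
  und <- c_index(rnorm(5), rep(2, 5))
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
  # exposure normalisation: equal rates are unusable pairs
  expect_true(is.na(c_index(c(1, 2), c(1, 2), exposure = c(10, 20))))
  expect_error(c_index(1, 1), ">= 2 observations")
})

test_that("concordance index equals the exhaustive pair oracle with ties", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(3:40, 1)
    binary <- rep %% 2 == 0
    obs <- if (binary) rbinom(n, 1, 0.4) else rpois(n, 1.2)
    pred <- sample(seq_len(6), n, replace = TRUE) / 6  # forces ties
    expo <- if (binary) NULL else runif(n, 6, 48)
    expect_identical(c_index(pred, obs, expo), c_index_oracle(pred, obs, expo))
  }
})

test_that("concordance index is invariant under monotone transforms", {
  set.seed(8)
  pred <- runif(30)
  obs <- rpois(30, 1)
  base <- c_index(pred, obs)
  expect_identical(c_index(log(pred), obs), base)
  expect_identical(c_index(pred^3, obs), base)
  expect_identical(c_index(stats::qlogis(pred), obs), base)
})

test_that("goodness of fit reduces to closed forms on point-mass posteriors", {
  # logit-link CDP model with all coefficients zero predicts p = 0.5 for
  # every row: NLL must be log 2, MSE the hand-computed Brier score
  flat <- fake_fit("cdp", cdp_link = "logit")
  tab <- fixture_table()[1:40, ]
  g <- goodness_of_fit(flat, tab)
  expect_equal(g$nll, log(2), tolerance = 1e-12)
  y <- as.numeric(tab$cdp_event[!tab$cdp_censored])
  expect_equal(g$mse, mean((y - 0.5)^2), tolerance = 1e-12)

  # relapse model with known coefficients: predicted mean count is exact,
  # MSE matches the hand-computed mean squared deviation
  f <- fake_fit("relapse", b0 = -3.2, log_r = log(1.5))
  mu <- exp(-3.2) * tab$exposure_months
  g2 <- goodness_of_fit(f, tab)
  expect_equal(g2$mse, mean((tab$relapse_count - mu)^2), tolerance = 1e-10)
  nll_hand <- -mean(stats::dnbinom(tab$relapse_count, size = 1.5, mu = mu,
                                   log = TRUE))
  expect_equal(g2$nll, nll_hand, tolerance = 1e-10)
})

test_that("cross-validation discriminates on informative data, not on noise", {
  tab <- fixture_table()
  cv <- cross_validate(tab, fast_spec("relapse", seed = 2), k_folds = 2,
                       seed = 11)
  expect_gt(cv$out_of_sample$c_index, 0.55)
  expect_gt(cv$in_sample$c_index, cv$out_of_sample$c_index - 0.05)
  expect_true(cv$in_sample$mse >= 0 && cv$out_of_sample$nll > 0)
  expect_output(print(cv), "out-of-sample")

  # identical seeds give identical reports
  cv2 <- cross_validate(tab, fast_spec("relapse", seed = 2), k_folds = 2,
                        seed = 11)
  expect_equal(cv, cv2, tolerance = 0)

  # permuted outcomes carry no signal
  noise <- tab
  noise$relapse_count <- with_seed_test(5, sample(tab$relapse_count))
  noise$exposure_months <- mean(tab$exposure_months)
  cvn <- cross_validate(noise, fast_spec("relapse", seed = 3), k_folds = 2,
                        seed = 12)
  expect_lt(abs(cvn$out_of_sample$c_index - 0.5), 0.06)
})

test_that("random-initialisation intervals shrink with more data", {
  spec <- fixture_gen_spec()
  big <- fixture_table()
  small_cohort <- generate_cohort(generator_spec(n_patients = 90, seed = 77))
  small <- build_switch_table(small_cohort)

  expect_error(empirical_coefficient_intervals(big, fast_spec("relapse"),
                                               n_refits = 1),
               "n_refits")

  ci_big <- empirical_coefficient_intervals(big, fast_spec("relapse", seed = 4),
                                            n_refits = 6, seed = 21)
  ci_small <- empirical_coefficient_intervals(small, fast_spec("relapse", seed = 4),
                                              n_refits = 6, seed = 21)
  expect_true(all(ci_big$span >= 0))
  expect_identical(attr(ci_big, "n_refits"), 6)
  shared <- intersect(ci_big$coefficient, ci_small$coefficient)
  expect_lt(stats::median(ci_big$span[match(shared, ci_big$coefficient)]),
            stats::median(ci_small$span[match(shared, ci_small$coefficient)]))
})

test_that("monitoring a non-growing registry shows no performance drift", {
  cohort <- fixture_cohort()[1:250]
  series <- list(cohort, cohort, cohort)
  test_cohort <- fixture_cohort()[251:500]
  mon <- monitor_growth(series, fast_spec("relapse", seed = 8), n_refits = 4,
                        test_cohort = test_cohort, seed = 14)
  s <- mon$summary
  expect_identical(s$delta_in[1], 0)
  expect_identical(s$delta_out[1], 0)
  # same data at every cut: changes reflect only sampler noise
  expect_true(all(abs(s$delta_out) < 0.02))
  expect_true(all(abs(s$delta_in) < 0.02))
  expect_identical(nrow(s), 3L)
  expect_error(monitor_growth(series[1:2], fast_spec("relapse")), ">= 3")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(mon))
  expect_output(print(mon), "reference")
})
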