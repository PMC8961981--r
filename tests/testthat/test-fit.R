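test_that("negative-binomial zero probability has its closed forms", {
  expect_identical(nb_zero_prob(0, 1.7), 1)        # zero rate -> certain zero
  expect_identical(nb_zero_prob(1, 1), 0.5)        # geometric: (1/2)^1
  # Poisson limit at very large dispersion
  expect_equal(nb_zero_prob(0.7, 1e6), exp(-0.7), tolerance = 1e-3)
  # strictly decreasing in the mean
  mus <- seq(0.1, 5, by = 0.1)
  expect_true(all(diff(nb_zero_prob(mus, 2)) < 0))
})

test_that("fit rejects degenerate inputs with structured errors", {
  tab <- fixture_table()
  one_dmt <- tab[tab$assigned_dmt == tab$assigned_dmt[1], ]
  expect_error(fit_outcome_model(one_dmt, fast_spec("relapse")),
               ">= 2 assigned DMT levels")

  flat <- tab
  flat$edss <- 3.0  # constant column is collinear with the intercept
  expect_error(fit_outcome_model(flat, fast_spec("relapse")),
               "collinear.*edss")

  neg <- tab
  neg$exposure_months[3] <- 0
  expect_error(fit_outcome_model(neg, fast_spec("relapse")),
               "exposure_months > 0")
})

test_that("the exposure offset absorbs a doubling of observation time", {
  spec <- fixture_gen_spec()
  tab <- fixture_table()
  tab2 <- tab
  tab2$exposure_months <- tab$exposure_months * 2
  # redraw counts from the generator truth at the doubled exposure
  lp <- dmtrank:::truth_linpred(spec$relapse_effects, tab, tab$assigned_dmt)
  tab2$relapse_count <- with_seed_test(91, stats::rnbinom(
    nrow(tab2), size = spec$dispersion, mu = tab2$exposure_months * exp(lp)))

  f1 <- fixture_fit("relapse")
  f2 <- suppressWarnings(fit_outcome_model(tab2, fast_spec("relapse", seed = 6)))
  s1 <- summary(f1)$coefficients
  s2 <- summary(f2)$coefficients
  for (nm in c("edss", "relapses_last_12m", "age", "(Intercept)")) {
    z <- abs(s1[nm, "mean"] - s2[nm, "mean"]) /
      sqrt(s1[nm, "sd"]^2 + s2[nm, "sd"]^2)
    expect_lt(z, 3.5)
  }
})

test_that("analytic relapse-free probability matches posterior-predictive simulation", {
  fit <- fixture_fit("relapse")
  x <- fixture_table()[7, ]
  horizon <- 24
  analytic <- prob_event_free(fit, x, "natalizumab", horizon)

  nd <- x
  nd$assigned_dmt <- "natalizumab"
  nd$exposure_months <- horizon
  nsim <- 40000
  sims <- simulate(fit, nsim = nsim, seed = 123, newdata = nd)
  frac0 <- mean(sims == 0)
  mc_se <- sqrt(frac0 * (1 - frac0) / nsim)
  # posterior spread contributes too; 3 MC SEs plus a small allowance
  expect_lt(abs(analytic$probability - frac0), 3 * mc_se + 0.01)
  expect_true(analytic$ci90[1] <= analytic$probability)
  expect_true(analytic$ci90[2] >= analytic$probability)
  expect_true(analytic$probability > 0 && analytic$probability < 1)
})

test_that("event-free probability is decreasing in horizon and 1 at horizon 0", {
  for (oc in c("relapse", "cdp")) {
    fit <- fixture_fit(oc)
    x <- fixture_table()[3, ]
    probs <- vapply(c(0, 12, 24, 48, 72), function(h) {
      prob_event_free(fit, x, "fingolimod", h)$probability
    }, 0)
    expect_identical(probs[1], 1)
    expect_true(all(diff(probs) < 0))
  }
  expect_error(prob_event_free(fixture_fit("relapse"), fixture_table()[1, ],
                               "nonexistent_dmt", 24),
               "catalogue")
})

test_that("prediction explanations decompose the linear predictor additively", {
  fit <- fixture_fit("relapse")
  cn <- fit$constants

  # a patient sitting exactly at the reference point
  ref <- fixture_table()[1, ]
  for (v in dmtrank:::CONT_PREDICTORS) ref[[v]] <- cn$center[[v]]
  ref$sex <- "female"
  ref$any_previous_second_line <- FALSE
  ref$current_dmt <- cn$prev_ref
  e0 <- explain_prediction(fit, ref, "natalizumab")
  expect_equal(e0$contribution, rep(0, nrow(e0)), tolerance = 1e-12)

  # only age off reference: a single nonzero contribution of beta_age * z
  aged <- ref
  aged$age <- cn$center[["age"]] + 10
  e1 <- explain_prediction(fit, aged, "natalizumab")
  nonzero <- e1$predictor[abs(e1$contribution) > 1e-12]
  expect_identical(nonzero, "age")
  b <- coef(fit)
  expect_equal(e1$contribution[e1$predictor == "age"],
               unname(b["age"]) * 10 / cn$scale[["age"]], tolerance = 1e-10)

  # additivity on an arbitrary patient: contributions sum to linpred minus
  # intercept and DMT effect, computed independently from posterior means
  x <- fixture_table()[11, ]
  e2 <- explain_prediction(fit, x, "fingolimod")
  X <- dmtrank:::build_design(transform(x, assigned_dmt = "fingolimod"), cn)$X
  lp_direct <- drop(X %*% b[fit$idx$beta])
  expect_equal(sum(e2$contribution), lp_direct, tolerance = 1e-10)
  expect_true(all(e2$percentile >= 0 & e2$percentile <= 100, na.rm = TRUE))
})

test_that("fit methods print, summarise, simulate and leave residuals centred", {
  fit <- fixture_fit("relapse")
  expect_output(print(fit), "relapse model")
  s <- summary(fit)
  expect_true(all(c("mean", "sd", "q5", "q95", "rhat") %in% colnames(s$coefficients)))
  expect_output(print(s), "negative-binomial")
  expect_identical(length(coef(fit)), ncol(fit$draws))

  tab <- fixture_table()[1:50, ]
  sims <- simulate(fit, nsim = 3, seed = 1, newdata = tab)
  expect_identical(dim(sims), c(50L, 3L))
  expect_true(all(sims >= 0))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1, newdata = tab))

  r <- residuals(fit, fixture_table())
  expect_lt(abs(mean(r)), 0.25)

  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("informative priors pull a sparse DMT towards the supplied location", {
  tab <- fixture_table()
  # starve one DMT of data, then anchor it with an informative prior
  rare <- tab[tab$assigned_dmt != "cladribine" |
                seq_len(nrow(tab)) %in% head(which(tab$assigned_dmt == "cladribine"), 2), ]
  f_flat <- suppressWarnings(fit_outcome_model(rare, fast_spec("relapse", seed = 9)))
  f_info <- suppressWarnings(fit_outcome_model(
    rare, fast_spec("relapse", seed = 9,
                    informative_priors = list(cladribine = c(-1.5, 0.2)))))
  expect_lt(abs(mean(f_info$draws[, "dmt_cladribine"]) - (-1.5)), 0.55)
  expect_lt(mean(f_info$draws[, "dmt_cladribine"]),
            mean(f_flat$draws[, "dmt_cladribine"]))
})

test_that("quadrupling prior scales leaves the induced therapy ranking stable", {
  tab <- fixture_table()
  f1 <- fixture_fit("relapse")
  f4 <- suppressWarnings(fit_outcome_model(
    tab, fast_spec("relapse", seed = 5, prior_scale_mult = 4)))
  idxs <- seq(2, 60, by = 10)
  rho <- numeric(length(idxs))
  for (k in seq_along(idxs)) {
    p1 <- drop(ranking_matrix(f1, tab[idxs[k], ], horizon_months = 48))
    p4 <- drop(ranking_matrix(f4, tab[idxs[k], ], horizon_months = 48))
    rho[k] <- stats::cor(p1, p4, method = "spearman")
    # probabilities barely move under the prior change
    expect_lt(max(abs(p1 - p4)), 0.05)
    # if the top choice swaps, it swaps between near-tied therapies only
    t1 <- names(which.max(p1))
    t4 <- names(which.max(p4))
    if (t1 != t4) {
      expect_lt(abs(p1[t1] - p1[t4]), 0.02)
      expect_lt(abs(p4[t1] - p4[t4]), 0.02)
    }
  }
  expect_gt(mean(rho), 0.9)
})
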