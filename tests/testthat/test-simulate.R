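test_that("a fixed seed reproduces the cohort exactly", {
  spec <- generator_spec(n_patients = 40, seed = 42)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
})

test_that("growth series grows by the accrual rate and only ever adds patients", {
  spec <- generator_spec(n_patients = 200, seed = 3)
  series <- generate_growth_series(spec, n_cuts = 5, growth_per_cut = 0.013)
  sizes <- vapply(series, length, 0L)
  expect_identical(sizes, as.integer(round(200 * 1.013^(0:4))))
  for (k in 2:5) {
    prev_ids <- names(series[[k - 1]])
    expect_identical(names(series[[k]])[seq_along(prev_ids)], prev_ids)
    # shared patients are byte-identical across cuts
    expect_identical(series[[k]][[10]], series[[k - 1]][[10]])
  }
  single <- generate_growth_series(spec, n_cuts = 1)
  expect_identical(length(single), 1L)
  expect_identical(length(single[[1]]), 200L)
})

test_that("null generator shows no treatment-arm differences beyond noise", {
  spec <- generator_spec(n_patients = 1500, seed = 21, assignment = list(strength = 0))
  spec$relapse_effects$dmt[] <- 0
  spec$cdp_effects$dmt[] <- 0
  tab <- build_switch_table(generate_cohort(spec))
  arr <- 12 * tab$relapse_count / tab$exposure_months
  overall <- mean(arr)
  for (d in unique(tab$assigned_dmt)) {
    sel <- tab$assigned_dmt == d
    se <- stats::sd(arr[sel]) / sqrt(sum(sel))
    expect_lt(abs(mean(arr[sel]) - overall), 4 * se + 1e-12)
  }
})

test_that("a relapse-rate multiplier of 0.5 shows up as a halved empirical rate", {
  spec <- generator_spec(n_patients = 2500, seed = 8, assignment = list(strength = 0))
  spec$relapse_effects$dmt[] <- 0
  spec$relapse_effects$dmt["natalizumab"] <- log(0.5)
  tab <- build_switch_table(generate_cohort(spec))
  rate <- function(sel) sum(tab$relapse_count[sel]) / sum(tab$exposure_months[sel])
  ratio <- rate(tab$assigned_dmt == "natalizumab") /
    rate(tab$assigned_dmt != "natalizumab")
  expect_lt(abs(ratio - 0.5), 0.07)
})

test_that("generated 3mCDP events are exactly recoverable from the EDSS series", {
  # every event the truth model drew was embedded as a sustained confirmed
  # step, so event rates must match the truth-implied probabilities closely
  spec <- generator_spec(n_patients = 800, seed = 13)
  cohort <- generate_cohort(spec)
  tab <- build_switch_table(cohort)
  p_true <- vapply(seq_len(nrow(tab)), function(i) {
    lam <- exp(dmtrank:::truth_linpred(spec$cdp_effects, tab[i, ],
                                       tab$assigned_dmt[i]))
    1 - exp(-lam * tab$exposure_months[i])
  }, 0)
  expect_false(any(tab$cdp_censored))
  diff <- mean(tab$cdp_event) - mean(p_true)
  se <- sqrt(sum(p_true * (1 - p_true))) / nrow(tab)
  expect_lt(abs(diff), 4 * se)
})

test_that("confounded assignment channels sicker patients to second-line DMTs", {
  tab <- fixture_table()
  second <- dmtrank:::is_second_line(tab$assigned_dmt, default_dmt_catalogue())
  expect_gt(mean(tab$edss[second]), mean(tab$edss[!second]))
  expect_gt(mean(tab$relapses_last_12m[second]),
            mean(tab$relapses_last_12m[!second]))
})

test_that("adherence generator carries its truth and a confounded label", {
  base <- fixture_table()
  tab <- generate_adherence_table(n = nrow(base), delta_log_rr = -0.5,
                                  seed = 4, base_table = base)
  expect_true(is.logical(tab$followed))
  expect_identical(attr(tab, "truth")$delta_log_rr, -0.5)
  # same covariates, fresh outcomes
  expect_identical(tab$edss, base$edss)
  # the label is genuinely confounded: sicker patients follow more often
  expect_gt(mean(tab$edss[tab$followed]), mean(tab$edss[!tab$followed]))
  # replicates with different seeds share covariates but differ in outcomes
  tab2 <- generate_adherence_table(n = nrow(base), seed = 5, base_table = base)
  expect_false(identical(tab$relapse_count, tab2$relapse_count))
})
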