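# Shared fixtures, built once per test run and cached. Fits use reduced
# sampler settings: point estimates and interval shapes are what the unit
# tests assert, so short well-preconditioned chains suffice; the production
# convergence gate is exercised separately.

.fixture_env <- new.env(parent = emptyenv())

fast_spec <- function(outcome, seed = 1, ...) {
  model_spec(outcome, chains = 2, draws = 500, warmup = 250, thin = 1,
             leap_max = 6, seed = seed, rhat_threshold = 1.2, ...)
}

fixture_gen_spec <- function() generator_spec(n_patients = 700, seed = 42)

fixture_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(fixture_gen_spec())
  }
  .fixture_env$cohort
}

fixture_table <- function() {
  if (is.null(.fixture_env$table)) {
    .fixture_env$table <- build_switch_table(fixture_cohort())
  }
  .fixture_env$table
}

fixture_fit <- function(outcome) {
  key <- paste0("fit_", outcome)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- suppressWarnings(
      fit_outcome_model(fixture_table(), fast_spec(outcome, seed = 5))
    )
  }
  .fixture_env[[key]]
}

# A minimal dmt_fit whose posterior is a point mass at chosen coefficient
# values — lets tests pin predictions to hand-computable numbers.
fake_fit <- function(outcome = "relapse", cdp_link = "cloglog",
                     b0 = 0, beta = NULL, alpha = NULL, log_r = 0,
                     n_draws = 2) {
  tab <- fixture_table()[1:20, ]
  catalogue <- default_dmt_catalogue()
  spec <- model_spec(outcome, cdp_link = cdp_link)
  constants <- dmtrank:::design_constants(tab, catalogue)
  X <- dmtrank:::build_design(tab, constants)$X
  idx <- dmtrank:::make_param_map(ncol(X), nrow(catalogue), outcome,
                                  cdp_link, FALSE, colnames(X),
                                  constants$dmt_levels)
  th <- numeric(idx$n_par)
  th[idx$b0] <- b0
  if (!is.null(beta)) th[idx$beta][seq_along(beta)] <- beta
  if (!is.null(alpha)) th[idx$alpha] <- alpha
  if (!is.null(idx$log_r)) th[idx$log_r] <- log_r
  draws <- matrix(rep(th, each = n_draws), nrow = n_draws)
  colnames(draws) <- idx$names
  structure(
    list(draws = draws, idx = idx, constants = constants, spec = spec,
         catalogue = catalogue,
         diagnostics = list(rhat = rep(1, idx$n_par), accept = 1,
                            converged = TRUE),
         fingerprint = list(n = nrow(tab), outcome = outcome)),
    class = "dmt_fit"
  )
}

# Independent concordance-index oracle: plain double loop over all pairs.
c_index_oracle <- function(pred, obs, exposure = NULL) {
  if (!is.null(exposure)) obs <- obs / exposure
  num <- 0
  den <- 0
  n <- length(obs)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (obs[i] == obs[j]) next
      den <- den + 1
      if (pred[i] == pred[j]) {
        num <- num + 0.5
      } else if ((pred[i] > pred[j]) == (obs[i] > obs[j])) {
        num <- num + 1
      }
    }
  }
  if (den == 0) return(structure(NA_real_, undefined = TRUE))
  num / den
}

# Hand-built patient: diagnosis 2010-01-01, interferon then natalizumab
# (switch 2015-06-01), EDSS 2.0 recorded before the switch, relapses 100 and
# 400 days before the switch.
reference_patient <- function(edss_score = 2.0,
                              switch_date = as.Date("2015-06-01")) {
  patient_record(
    patient_id = "ref1", sex = "female", birth_year = 1980,
    diagnosis_date = as.Date("2010-01-01"),
    episodes = data.frame(
      dmt_id = c("interferon_beta", "natalizumab"),
      start_date = c(as.Date("2012-01-01"), switch_date),
      end_date = c(switch_date, as.Date("2017-06-01"))
    ),
    relapses = c(switch_date - 100, switch_date - 400),
    edss = data.frame(
      date = c(switch_date - 120, switch_date - 10,
               switch_date + 180, switch_date + 360),
      score = rep(edss_score, 4)
    )
  )
}

with_seed_test <- function(seed, expr) withr::with_seed(seed, expr)

fork_seed_test <- function(seed, index) dmtrank:::fork_seed(seed, index)
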