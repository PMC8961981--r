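#' Model specification for the Bayesian outcome models
#'
#' Collects every tunable of the two hierarchical GLMs. The relapse model is
#' a negative-binomial regression of the post-switch relapse count with a
#' log-exposure offset (mean/dispersion parameterisation,
#' `variance = mu + mu^2/r`); the 3mCDP model is a binary regression with,
#' by default, a complementary-log-log link and the same log-exposure offset
#' (a discrete constant-hazard formulation), or optionally a logit link with
#' log-exposure as a covariate. Both models carry partially pooled
#' DMT-specific intercepts (`alpha_d ~ N(0, sigma)` with a lognormal prior
#' on `sigma`); DMT-specific slopes for EDSS and recent relapse count can be
#' switched on. Informative priors for sparsely observed, newly introduced
#' DMTs are user-specified normal priors on the DMT intercept.
#'
#' @param outcome `"relapse"` or `"cdp"`.
#' @param cdp_link `"cloglog"` (default) or `"logit"`.
#' @param dmt_slopes Add partially pooled DMT-specific slopes for EDSS and
#'   relapses in the last 12 months.
#' @param prior_scale_intercept,prior_scale_beta Normal prior SDs for the
#'   intercept and the standardised fixed effects.
#' @param prior_scale_alpha Scale of the DMT-pooling SD prior: the pooling
#'   SD is lognormal with median `0.5 * prior_scale_alpha` and unit log-SD
#'   (a scale prior vanishing at zero, keeping the joint posterior mode
#'   finite in the hierarchical funnel).
#' @param prior_r_location,prior_r_scale Normal prior on `log r` (relapse
#'   dispersion).
#' @param prior_scale_mult Multiplies every prior scale (prior-robustness
#'   checks).
#' @param informative_priors Named list `dmt_id -> c(location, scale)`
#'   overriding the pooled prior for selected DMT intercepts.
#' @param chains,draws,warmup Sampler layout: independent chains, stored
#'   post-warmup draws per chain, adaptation iterations.
#' @param thin HMC steps per stored draw.
#' @param leap_max Maximum leapfrog steps per HMC proposal (trajectory
#'   lengths are jittered uniformly over `1:leap_max`).
#' @param target_accept Step-size adaptation target of the HMC kernel.
#' @param seed Sampler seed (mode-search initialisation and chain streams).
#' @param rhat_threshold Convergence threshold on the split-chain statistic.
#' @return Object of class `dmt_model_spec`.
#' @export
model_spec <- function(outcome = c("relapse", "cdp"),
                       cdp_link = c("cloglog", "logit"),
                       dmt_slopes = FALSE,
                       prior_scale_intercept = 5, prior_scale_beta = 2.5,
                       prior_scale_alpha = 1,
                       prior_r_location = 0, prior_r_scale = 2,
                       prior_scale_mult = 1,
                       informative_priors = list(),
                       chains = 4, draws = 1000, warmup = 300, thin = 1,
                       leap_max = 10, target_accept = 0.8,
                       seed = 1, rhat_threshold = 1.01) {
  structure(
    list(outcome = match.arg(outcome), cdp_link = match.arg(cdp_link),
         dmt_slopes = isTRUE(dmt_slopes),
         prior_scale_intercept = prior_scale_intercept,
         prior_scale_beta = prior_scale_beta,
         prior_scale_alpha = prior_scale_alpha,
         prior_r_location = prior_r_location, prior_r_scale = prior_r_scale,
         prior_scale_mult = prior_scale_mult,
         informative_priors = informative_priors,
         chains = as.integer(chains), draws = as.integer(draws),
         warmup = as.integer(warmup), thin = as.integer(thin),
         leap_max = as.integer(leap_max), target_accept = target_accept,
         seed = as.integer(seed), rhat_threshold = rhat_threshold),
    class = "dmt_model_spec"
  )
}

#' Fit a hierarchical Bayesian outcome model
#'
#' Fits the negative-binomial relapse model or the binary 3mCDP model to a
#' switch table (see [build_switch_table()]). Continuous predictors are
#' standardised by training mean/SD, the previous therapy enters as dummies
#' against the most frequent category, and the assigned DMT receives a
#' partially pooled intercept for every catalogue therapy (therapies absent
#' from the training data keep their pooled prior). Posterior draws come
#' from preconditioned Hamiltonian Monte Carlo chains: the posterior
#' mode is located in the non-centred parameterisation (whose mode is
#' regular), transported to centred coordinates with its Laplace covariance
#' as preconditioner, and each chain's mode search starts from its own
#' random initial point. Convergence is monitored with the split-chain
#' potential-scale-reduction statistic; a fit exceeding the threshold is
#' returned but flagged non-converged.
#'
#' @param table A `switch_table`.
#' @param spec A [model_spec()].
#' @param catalogue A [dmt_catalogue()]; defines the DMT levels.
#' @return Object of class `dmt_fit`: posterior draws, frozen design
#'   constants, diagnostics and a training-data fingerprint.
#' @seealso [prob_event_free()], [rank_therapies()], [predict.dmt_fit()]
#' @export
fit_outcome_model <- function(table, spec = model_spec(),
                              catalogue = default_dmt_catalogue()) {
  stopifnot(is.data.frame(table))
  if (any(table$exposure_months <= 0)) {
    stop_input("all rows must have exposure_months > 0")
  }
  if (spec$outcome == "cdp" && any(table$cdp_censored)) {
    table <- table[!table$cdp_censored, , drop = FALSE]
  }
  obs_lev <- unique(table$assigned_dmt)
  if (length(obs_lev) < 2) {
    stop_input("need >= 2 assigned DMT levels with observations (got %d)",
               length(obs_lev))
  }
  assert_in_catalogue(obs_lev, catalogue)

  constants <- design_constants(table, catalogue)
  design <- build_design(table, constants)
  check_collinear(design$X)

  y <- if (spec$outcome == "relapse") table$relapse_count else
    as.numeric(table$cdp_event)
  idx <- make_param_map(ncol(design$X), length(constants$dmt_levels),
                        spec$outcome, spec$cdp_link, spec$dmt_slopes,
                        colnames(design$X), constants$dmt_levels)
  post_nc <- make_posterior(design, y, log(table$exposure_months),
                            spec$outcome, spec, idx, centred = FALSE)
  post <- make_posterior(design, y, log(table$exposure_months),
                         spec$outcome, spec, idx, centred = TRUE)

  chains <- vector("list", spec$chains)
  accepts <- numeric(spec$chains)
  for (c in seq_len(spec$chains)) {
    ms <- find_map(post_nc, idx$n_par, fork_seed(spec$seed, 1000 + c))
    start <- post_nc$to_centred(ms$map)
    J <- post_nc$centred_jacobian(ms$map)
    S0 <- J %*% laplace_cov(ms$H) %*% t(J)
    res <- run_chain(post, start, (S0 + t(S0)) / 2, spec$draws,
                     spec$warmup, fork_seed(spec$seed, 2000 + c),
                     spec$target_accept, spec$thin,
                     spec$leap_max %||% 10L)
    chains[[c]] <- res$draws
    accepts[c] <- res$accept
  }
  draws <- do.call(rbind, chains)
  colnames(draws) <- idx$names
  rhat <- split_rhat(chains)
  names(rhat) <- idx$names
  converged <- all(rhat <= spec$rhat_threshold, na.rm = TRUE)
  if (!converged) {
    warning(sprintf("fit flagged non-converged: max split-Rhat = %.3f",
                    max(rhat, na.rm = TRUE)))
  }
  if (mean(accepts) < 0.2) {
    warning(sprintf("low HMC acceptance (%.1f%%); treat draws with care",
                    100 * mean(accepts)))
  }

  structure(
    list(draws = draws, idx = idx, constants = constants,
         spec = spec, catalogue = catalogue,
         diagnostics = list(rhat = rhat, accept = accepts,
                            converged = converged),
         fingerprint = list(n = nrow(table), outcome = spec$outcome,
                            y_sum = sum(y),
                            exposure_sum = sum(table$exposure_months)),
         call = match.call()),
    class = "dmt_fit"
  )
}

#' @export
print.dmt_fit <- function(x, ...) {
  cat(sprintf("<dmt_fit: %s model>\n", x$spec$outcome))
  cat(sprintf("  n = %d switches, %d posterior draws (%d chains)\n",
              x$fingerprint$n, nrow(x$draws), x$spec$chains))
  cat(sprintf("  converged: %s (max split-Rhat %.3f, mean acceptance %.2f)\n",
              x$diagnostics$converged, max(x$diagnostics$rhat, na.rm = TRUE),
              mean(x$diagnostics$accept)))
  invisible(x)
}

#' @export
summary.dmt_fit <- function(object, ...) {
  d <- object$draws
  tab <- data.frame(
    mean = colMeans(d),
    sd = apply(d, 2, stats::sd),
    q5 = apply(d, 2, stats::quantile, 0.05),
    q50 = apply(d, 2, stats::quantile, 0.50),
    q95 = apply(d, 2, stats::quantile, 0.95),
    rhat = object$diagnostics$rhat
  )
  structure(list(outcome = object$spec$outcome, coefficients = tab,
                 n = object$fingerprint$n,
                 converged = object$diagnostics$converged),
            class = "summary.dmt_fit")
}

#' @export
print.summary.dmt_fit <- function(x, ...) {
  cat(sprintf("Hierarchical Bayesian %s model (n = %d)\n\n",
              if (x$outcome == "relapse") "negative-binomial relapse"
              else "3mCDP", x$n))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.dmt_fit <- function(object, ...) {
  colMeans(object$draws)
}

#' Posterior-mean linear predictor (without exposure) for table rows
#' @noRd
linpred_draws <- function(fit, table, dmt = NULL) {
  if (!is.null(dmt)) table$assigned_dmt <- dmt
  design <- build_design(table, fit$constants)
  d <- fit$draws
  idx <- fit$idx
  eta <- matrix(d[, idx$b0], nrow(d), nrow(table)) +
    d[, idx$beta, drop = FALSE] %*% t(design$X) +
    d[, idx$alpha, drop = FALSE][, design$dmt, drop = FALSE]
  if (!is.null(idx$s_edss)) {
    eta <- eta + t(t(d[, idx$s_edss, drop = FALSE][, design$dmt, drop = FALSE]) *
                     design$X[, "edss"]) +
      t(t(d[, idx$s_rel, drop = FALSE][, design$dmt, drop = FALSE]) *
          design$X[, "relapses_last_12m"])
  }
  eta  # S x n matrix, no exposure term
}

#' Predict event-free probabilities from a fitted model
#'
#' For every row of `newdata` (a switch table or predictor rows plus an
#' `assigned_dmt` column, unless `dmt` overrides it) returns the posterior
#' mean and 90% credible interval of the probability of remaining event-free
#' over `horizon_months` on the assigned DMT. `type = "mean"` instead
#' returns the expected relapse count (or event probability),
#' `type = "linpred"` the posterior-mean linear predictor.
#'
#' @param object A `dmt_fit`.
#' @param newdata Data frame of predictor rows.
#' @param horizon_months Prediction horizon in months (the tool's clinical
#'   range is 24-72 months).
#' @param dmt Optional DMT id applied to all rows.
#' @param type See above.
#' @param ... Unused.
#' @return A data.frame with columns `probability`, `lower90`, `upper90`
#'   (for `type = "event_free"`).
#' @export
predict.dmt_fit <- function(object, newdata, horizon_months = 24, dmt = NULL,
                            type = c("event_free", "mean", "linpred"), ...) {
  type <- match.arg(type)
  if (!is.null(dmt)) assert_in_catalogue(dmt, object$catalogue)
  eta <- linpred_draws(object, newdata, dmt)
  if (type == "linpred") {
    return(data.frame(linpred = colMeans(eta)))
  }
  p <- event_free_draws(object, eta, horizon_months)
  if (type == "mean") {
    m <- if (object$spec$outcome == "relapse") {
      exp(eta + log(horizon_months))
    } else {
      1 - p
    }
    return(data.frame(mean = colMeans(m)))
  }
  data.frame(probability = colMeans(p),
             lower90 = apply(p, 2, stats::quantile, 0.05),
             upper90 = apply(p, 2, stats::quantile, 0.95))
}

# S x n matrix of event-free probabilities per posterior draw.
event_free_draws <- function(fit, eta, horizon_months) {
  if (horizon_months < 0) stop_input("horizon_months must be >= 0")
  if (fit$spec$outcome == "relapse") {
    r <- exp(fit$draws[, fit$idx$log_r])
    mu <- exp(pmin(eta + log(max(horizon_months, 0)), 30))
    if (horizon_months == 0) mu[] <- 0
    (r / (r + mu))^r
  } else if (fit$spec$cdp_link == "cloglog") {
    if (horizon_months == 0) return(matrix(1, nrow(eta), ncol(eta)))
    lam <- exp(pmin(eta + log(horizon_months), 30))
    exp(-lam)
  } else {
    if (horizon_months == 0) return(matrix(1, nrow(eta), ncol(eta)))
    eta2 <- eta + fit$draws[, fit$idx$gamma_exposure] * log(horizon_months)
    1 - stats::plogis(eta2)
  }
}

#' Posterior-predictive simulation from a fitted model
#'
#' Draws outcome replicates (relapse counts or 3mCDP indicators) for the
#' rows of `newdata` over their `exposure_months`, one posterior draw per
#' simulation (cycled), giving posterior-predictive samples.
#'
#' @param object A `dmt_fit`.
#' @param nsim Number of replicate datasets.
#' @param seed Seed.
#' @param newdata Switch-table rows with `assigned_dmt`, `exposure_months`.
#' @param ... Unused.
#' @return `n x nsim` matrix of simulated outcomes.
#' @export
simulate.dmt_fit <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  eta <- linpred_draws(object, newdata)
  S <- nrow(eta)
  sim_one <- function(s) {
    e <- eta[s, ] + log(newdata$exposure_months)
    if (object$spec$outcome == "relapse") {
      r <- exp(object$draws[s, object$idx$log_r])
      stats::rnbinom(length(e), size = r, mu = exp(pmin(e, 30)))
    } else if (object$spec$cdp_link == "cloglog") {
      as.integer(stats::runif(length(e)) < -expm1(-exp(pmin(e, 30))))
    } else {
      eta2 <- eta[s, ] + object$draws[s, object$idx$gamma_exposure] *
        log(newdata$exposure_months)
      as.integer(stats::runif(length(eta2)) < stats::plogis(eta2))
    }
  }
  run <- function() {
    ss <- rep_len(seq_len(S), nsim)
    vapply(ss, sim_one, numeric(nrow(newdata)))
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  matrix(out, nrow = nrow(newdata), ncol = nsim)
}

# S x n matrix of event probabilities (CDP) or expected counts (relapse)
# over each row's own exposure time.
outcome_mean_draws <- function(fit, eta, exposure_months) {
  le <- log(exposure_months)
  if (fit$spec$outcome == "relapse") {
    exp(pmin(sweep(eta, 2, le, "+"), 30))
  } else if (fit$spec$cdp_link == "cloglog") {
    -expm1(-exp(pmin(sweep(eta, 2, le, "+"), 30)))
  } else {
    stats::plogis(eta + tcrossprod(fit$draws[, fit$idx$gamma_exposure], le))
  }
}

#' @export
residuals.dmt_fit <- function(object, newdata, ...) {
  eta <- linpred_draws(object, newdata)
  m <- colMeans(outcome_mean_draws(object, eta, newdata$exposure_months))
  if (object$spec$outcome == "relapse") {
    r <- exp(mean(object$draws[, object$idx$log_r]))
    (newdata$relapse_count - m) / sqrt(m + m^2 / r)
  } else {
    (as.numeric(newdata$cdp_event) - m) / sqrt(pmax(m * (1 - m), 1e-12))
  }
}

#' @export
plot.dmt_fit <- function(x, ...) {
  s <- summary(x)$coefficients
  o <- seq_len(nrow(s))
  graphics::plot(s$mean, o, xlim = range(s$q5, s$q95), yaxt = "n",
                 xlab = "posterior mean and 90% credible interval", ylab = "",
                 pch = 19, main = sprintf("%s model coefficients",
                                          x$spec$outcome), ...)
  graphics::segments(s$q5, o, s$q95, o)
  graphics::axis(2, at = o, labels = rownames(s), las = 2, cex.axis = 0.6)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Negative-binomial zero probability
#'
#' The probability that a negative-binomial count with mean `mu` and
#' dispersion `r` (variance `mu + mu^2/r`) equals zero:
#' `(r / (r + mu))^r`. This closed form is what the relapse model uses as
#' the probability of staying relapse-free; it equals the fraction of
#' posterior-predictive counts that are zero, without simulation.
#'
#' @param mu Mean (vectorised).
#' @param r Dispersion (> 0).
#' @return Probability in `(0, 1]`.
#' @export
nb_zero_prob <- function(mu, r) {
  stopifnot(all(r > 0), all(mu >= 0))
  (r / (r + mu))^r
}
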