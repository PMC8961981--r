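#' Probability of remaining event-free under a DMT
#'
#' The clinical quantity at the heart of the tool. For the relapse model the
#' event-free probability is the negative-binomial zero probability per
#' posterior draw, `p_s = (r_s / (r_s + mu_s))^{r_s}` with
#' `mu_s = exp(x beta_s + alpha_{d,s} + log horizon)` — the analytic form of
#' "the fraction of predicted relapse counts equal to zero". For the 3mCDP
#' model it is the survival of the discrete hazard,
#' `exp(-horizon * exp(x beta'_s + alpha'_{d,s}))` under the default
#' complementary-log-log link. The point estimate is the posterior mean and
#' the interval the 5th-95th percentile of the per-draw probabilities.
#'
#' @param fit A [fit_outcome_model()] result.
#' @param x One predictor row (e.g. from [extract_predictors()]).
#' @param dmt DMT identifier from the catalogue.
#' @param horizon_months Horizon in months; the clinical range offered by the
#'   tool is 24-72 months (2-6 years).
#' @return List with `probability`, `ci90` (length-2), and `draws`.
#' @export
prob_event_free <- function(fit, x, dmt, horizon_months) {
  stopifnot(inherits(fit, "dmt_fit"), nrow(x) == 1)
  assert_in_catalogue(dmt, fit$catalogue)
  eta <- linpred_draws(fit, x, dmt = dmt)
  p <- event_free_draws(fit, eta, horizon_months)[, 1]
  list(probability = mean(p),
       ci90 = stats::quantile(p, c(0.05, 0.95), names = FALSE),
       draws = p)
}

#' Per-predictor contribution breakdown for one prediction
#'
#' Additively decomposes the linear predictor of a prediction into one term
#' per predictor: the posterior-mean coefficient times the predictor's
#' deviation from its reference (training mean for continuous predictors,
#' reference category otherwise). The contributions sum exactly to the
#' linear predictor minus the intercept and DMT effect. Each predictor also
#' gets the patient's percentile position within the training distribution,
#' for the "where does this patient sit" panel of a report.
#'
#' @inheritParams prob_event_free
#' @return `data.frame` with columns `predictor`, `value`, `contribution`,
#'   `percentile`.
#' @export
explain_prediction <- function(fit, x, dmt) {
  stopifnot(inherits(fit, "dmt_fit"), nrow(x) == 1)
  assert_in_catalogue(dmt, fit$catalogue)
  cn <- fit$constants
  b <- colMeans(fit$draws)[fit$idx$beta]
  names(b) <- fit$idx$names[fit$idx$beta]
  x$assigned_dmt <- dmt
  X <- build_design(x, cn)$X[1, ]

  pct <- function(v) {
    q <- cn$quantiles[[v]]
    100 * stats::approx(q, seq(0, 1, by = 0.01), xout = x[[v]], rule = 2,
                        ties = "ordered")$y
  }
  rows <- lapply(predictor_names(), function(v) {
    if (v %in% CONT_PREDICTORS) {
      contrib <- unname(b[v] * X[v])
      data.frame(predictor = v, value = as.character(x[[v]]),
                 contribution = contrib, percentile = pct(v))
    } else if (v == "sex") {
      data.frame(predictor = v, value = x$sex,
                 contribution = unname(b["sex_male"] * X["sex_male"]),
                 percentile = 100 * (if (x$sex == "male") 1 - cn$frac_male / 2
                                     else (1 - cn$frac_male) / 2))
    } else if (v == "any_previous_second_line") {
      data.frame(predictor = v, value = as.character(x[[v]]),
                 contribution = unname(b["any_previous_second_line"] *
                                         X["any_previous_second_line"]),
                 percentile = NA_real_)
    } else {  # current_dmt
      col <- paste0("prev_", x$current_dmt)
      contrib <- if (col %in% names(b)) unname(b[col]) else 0
      data.frame(predictor = v, value = x$current_dmt,
                 contribution = contrib, percentile = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "linpred_minus_intercept") <- sum(out$contribution)
  out
}
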