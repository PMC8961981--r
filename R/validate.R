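#' Concordance index
#'
#' The proportion of concordant pairs among all usable evaluation pairs. A
#' pair is usable when the observed outcomes differ (for the relapse model
#' the observed outcome is the exposure-normalised relapse rate; pass
#' `exposure` to enable this); it is concordant when the predictions order
#' the same way, and a prediction tie contributes 0.5. A value of 1
#' indicates perfect predictions, 0.5 chance-level discrimination.
#'
#' @param predictions Numeric predicted scores (any strictly monotone
#'   transform of the model's predicted rate/probability gives the same
#'   value).
#' @param observed Observed counts (relapse) or 0/1 events (CDP).
#' @param exposure Optional exposure times; when given, observed outcomes
#'   are compared as rates `observed / exposure`.
#' @return The concordance index in `[0, 1]`, or `NA` with attribute
#'   `undefined = TRUE` when no usable pair exists (all outcomes identical).
#' @export
c_index <- function(predictions, observed, exposure = NULL) {
  n <- length(observed)
  if (n < 2 || length(predictions) != n) {
    stop_input("need >= 2 observations with matching predictions")
  }
  obs <- if (is.null(exposure)) as.numeric(observed) else observed / exposure
  conc <- 0
  usable <- 0
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d_obs <- obs[i] - obs[j]
    use <- d_obs != 0
    if (!any(use)) next
    d_pred <- predictions[i] - predictions[j]
    agree <- sign(d_pred[use]) * sign(d_obs[use])
    conc <- conc + sum(agree > 0) + 0.5 * sum(agree == 0)
    usable <- usable + sum(use)
  }
  if (usable == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  conc / usable
}

#' Goodness of fit of a model on a table
#'
#' Mean squared error in outcome units (relapses for the relapse model,
#' event indicators for the CDP model) between observed outcomes and
#' posterior-mean predictions over each row's own exposure, and the mean
#' negative log posterior-predictive mass.
#'
#' @param fit A `dmt_fit`.
#' @param table A `switch_table`.
#' @param thin Maximum number of posterior draws used.
#' @return List with `mse` and `nll`.
#' @export
goodness_of_fit <- function(fit, table, thin = 400) {
  if (any(table$exposure_months <= 0)) {
    stop_input("test rows must have positive exposure")
  }
  if (fit$spec$outcome == "cdp") {
    table <- table[!table$cdp_censored, , drop = FALSE]
  }
  eta <- thin_draws_eta(fit, table, thin)
  m <- outcome_mean_draws(fit, eta$eta, table$exposure_months)
  if (fit$spec$outcome == "relapse") {
    y <- table$relapse_count
    pred <- colMeans(m)
    r <- exp(fit$draws[eta$keep, fit$idx$log_r])
    dens <- stats::dnbinom(rep(y, each = nrow(m)), size = r, mu = m)
    dim(dens) <- dim(m)
    nll <- -mean(log(pmax(colMeans(dens), 1e-300)))
    list(mse = mean((y - pred)^2), nll = nll)
  } else {
    y <- as.numeric(table$cdp_event)
    pred <- colMeans(m)
    lik <- sweep(m, 2, y, function(p, yy) ifelse(yy == 1, p, 1 - p))
    nll <- -mean(log(pmax(colMeans(lik), 1e-300)))
    list(mse = mean((y - pred)^2), nll = nll)
  }
}

# Thinned linear-predictor draws; returns draw indices kept.
thin_draws_eta <- function(fit, table, thin) {
  S <- nrow(fit$draws)
  keep <- if (S > thin) round(seq(1, S, length.out = thin)) else seq_len(S)
  f2 <- fit
  f2$draws <- fit$draws[keep, , drop = FALSE]
  list(eta = linpred_draws(f2, table), keep = keep)
}

# Out-of-sample prediction scores for the C-index: posterior-mean event rate
# per month (relapse) or event probability over own exposure (CDP).
predicted_scores <- function(fit, table, thin = 400) {
  eta <- thin_draws_eta(fit, table, thin)$eta
  if (fit$spec$outcome == "relapse") {
    colMeans(exp(pmin(eta, 30)))
  } else {
    colMeans(outcome_mean_draws(fit, eta, table$exposure_months))
  }
}

metric_row <- function(fit, table) {
  sc <- predicted_scores(fit, table)
  ci <- if (fit$spec$outcome == "relapse") {
    c_index(sc, table$relapse_count, table$exposure_months)
  } else {
    c_index(sc, as.numeric(table$cdp_event))
  }
  g <- goodness_of_fit(fit, table)
  list(c_index = as.numeric(ci), mse = g$mse, nll = g$nll)
}

#' Patient-level cross-validation
#'
#' In-sample metrics from a fit on the full table; out-of-sample metrics
#' averaged over `k_folds` folds split **by patient** (a patient's rows are
#' never divided between training and test, respecting generalisation to
#' new patients). Folds whose test set contains a DMT unobserved in training
#' are still scored — the pooled prior stands in for the missing DMT
#' intercept — and flagged.
#'
#' @param table A `switch_table`.
#' @param spec A [model_spec()].
#' @param k_folds Number of folds (>= 2).
#' @param seed Seed for the patient split.
#' @param catalogue A [dmt_catalogue()].
#' @return Object of class `dmt_validation` with elements `in_sample`,
#'   `out_of_sample` (each `c_index`, `mse`, `nll`), `n_train`, `n_test`,
#'   `folds_flagged`, `seed`.
#' @export
cross_validate <- function(table, spec = model_spec(), k_folds = 5, seed = 1,
                           catalogue = default_dmt_catalogue()) {
  if (k_folds < 2) stop_input("k_folds must be >= 2")
  full <- fit_outcome_model(table, spec, catalogue)
  ins <- metric_row(full, table)

  pts <- unique(table$patient_id)
  fold_of <- with_seed(fork_seed(seed, 99),
                       sample(rep_len(seq_len(k_folds), length(pts))))
  names(fold_of) <- pts
  out <- vector("list", k_folds)
  flagged <- logical(k_folds)
  for (f in seq_len(k_folds)) {
    test <- table[fold_of[table$patient_id] == f, , drop = FALSE]
    train <- table[fold_of[table$patient_id] != f, , drop = FALSE]
    sp <- spec
    sp$seed <- fork_seed(seed, 500 + f)
    fit_f <- fit_outcome_model(train, sp, catalogue)
    flagged[f] <- length(setdiff(unique(test$assigned_dmt),
                                 unique(train$assigned_dmt))) > 0
    out[[f]] <- metric_row(fit_f, test)
  }
  oos <- lapply(c(c_index = "c_index", mse = "mse", nll = "nll"), function(k)
    mean(vapply(out, function(o) o[[k]], 0), na.rm = TRUE))
  structure(
    list(outcome = spec$outcome, in_sample = ins, out_of_sample = oos,
         n_train = nrow(table), n_test = round(nrow(table) / k_folds),
         k_folds = k_folds, folds_flagged = which(flagged), seed = seed,
         per_fold = out),
    class = "dmt_validation"
  )
}

#' @export
print.dmt_validation <- function(x, ...) {
  cat(sprintf("<dmt_validation: %s model, %d-fold by patient, n = %d>\n",
              x$outcome, x$k_folds, x$n_train))
  cat(sprintf("  in-sample:     C-index %.3f  MSE %.3f  NLL %.3f\n",
              x$in_sample$c_index, x$in_sample$mse, x$in_sample$nll))
  cat(sprintf("  out-of-sample: C-index %.3f  MSE %.3f  NLL %.3f\n",
              x$out_of_sample$c_index, x$out_of_sample$mse, x$out_of_sample$nll))
  if (length(x$folds_flagged)) {
    cat("  folds with DMT unseen in training:",
        paste(x$folds_flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Empirical 90% coefficient intervals across random-initialisation refits
#'
#' Fits the same model `n_refits` times on the same data, varying only the
#' random initialisation stream (mode-search starting points and chain
#' seeds; the data are never resampled), and summarises each coefficient's
#' point estimates across refits by their empirical 5th-95th percentile
#' interval. A small span means the data, not the initialisation, determine
#' the coefficient. Non-convergent refits are excluded; more than 20%
#' exclusions aborts the run.
#'
#' @param table A `switch_table`.
#' @param spec A [model_spec()].
#' @param n_refits Number of refits (>= 2; 20 or more is the intended
#'   monitoring regime).
#' @param seed Master seed for the initialisation streams.
#' @param catalogue A [dmt_catalogue()].
#' @return `data.frame` of class `dmt_coef_intervals`: `coefficient`,
#'   `estimate` (median), `lower`, `upper`, `span`; attributes `n_refits`,
#'   `n_excluded`.
#' @export
empirical_coefficient_intervals <- function(table, spec = model_spec(),
                                            n_refits = 20, seed = 1,
                                            catalogue = default_dmt_catalogue()) {
  if (n_refits < 2) stop_input("n_refits must be >= 2 (>= 20 recommended)")
  ests <- vector("list", n_refits)
  excluded <- 0L
  for (j in seq_len(n_refits)) {
    sp <- spec
    sp$seed <- fork_seed(seed, 7000 + j)
    fit_j <- suppressWarnings(fit_outcome_model(table, sp, catalogue))
    if (!fit_j$diagnostics$converged) {
      excluded <- excluded + 1L
      next
    }
    ests[[j]] <- coef(fit_j)
  }
  if (excluded > 0.2 * n_refits) {
    stop_input("%d of %d refits non-convergent (> 20%%)", excluded, n_refits)
  }
  E <- do.call(rbind, ests[!vapply(ests, is.null, TRUE)])
  lo <- apply(E, 2, stats::quantile, 0.05)
  hi <- apply(E, 2, stats::quantile, 0.95)
  structure(
    data.frame(coefficient = colnames(E), estimate = apply(E, 2, stats::median),
               lower = lo, upper = hi, span = hi - lo, row.names = NULL),
    class = c("dmt_coef_intervals", "data.frame"),
    n_refits = n_refits, n_excluded = excluded
  )
}

#' Robustness monitoring over an accruing registry
#'
#' For each data cut of a growing cohort series (see
#' [generate_growth_series()]), fits the model, computes in-sample metrics,
#' out-of-sample metrics (on `test_cohort` if supplied — a fixed set of
#' unseen patients — otherwise by patient-level cross-validation), and the
#' empirical coefficient-interval spans. The first cut is the reference
#' point: the monitoring quantities are the change in C-index versus that
#' reference and the trajectory of the median interval span.
#'
#' @param series List of cohorts of increasing size (>= 3 cuts).
#' @param spec A [model_spec()].
#' @param n_refits Refits per cut for the interval spans.
#' @param test_cohort Optional held-out cohort for out-of-sample metrics.
#' @param k_folds Folds when no `test_cohort` is given.
#' @param seed Seed.
#' @param catalogue A [dmt_catalogue()].
#' @return Object of class `dmt_monitor`: per-cut `data.frame` `summary`
#'   (`cut`, `n_patients`, `n_rows`, `c_index_in`, `c_index_out`,
#'   `delta_in`, `delta_out`, `median_span`) and the list of
#'   per-cut coefficient-interval tables.
#' @export
monitor_growth <- function(series, spec = model_spec(), n_refits = 20,
                           test_cohort = NULL, k_folds = 3, seed = 1,
                           catalogue = default_dmt_catalogue()) {
  if (length(series) < 3) stop_input("need >= 3 data cuts to monitor")
  test_table <- if (!is.null(test_cohort)) {
    build_switch_table(test_cohort, catalogue)
  } else {
    NULL
  }
  rows <- vector("list", length(series))
  intervals <- vector("list", length(series))
  for (k in seq_along(series)) {
    tab <- build_switch_table(series[[k]], catalogue)
    sp <- spec
    sp$seed <- fork_seed(seed, 300 + k)
    if (!is.null(test_table)) {
      fit_k <- fit_outcome_model(tab, sp, catalogue)
      ins <- metric_row(fit_k, tab)
      oos <- metric_row(fit_k, test_table)
    } else {
      cv <- cross_validate(tab, sp, k_folds, fork_seed(seed, 400 + k),
                           catalogue)
      ins <- cv$in_sample
      oos <- cv$out_of_sample
    }
    intervals[[k]] <- empirical_coefficient_intervals(
      tab, spec, n_refits, fork_seed(seed, 600 + k), catalogue)
    rows[[k]] <- data.frame(
      cut = k, n_patients = length(series[[k]]), n_rows = nrow(tab),
      c_index_in = ins$c_index, c_index_out = oos$c_index,
      mse_in = ins$mse, mse_out = oos$mse,
      median_span = stats::median(intervals[[k]]$span)
    )
  }
  s <- do.call(rbind, rows)
  s$delta_in <- s$c_index_in - s$c_index_in[1]
  s$delta_out <- s$c_index_out - s$c_index_out[1]
  structure(list(summary = s, intervals = intervals),
            class = "dmt_monitor")
}

#' @export
print.dmt_monitor <- function(x, ...) {
  cat("<dmt_monitor> per-cut robustness summary (cut 1 = reference):\n")
  print(round(x$summary, 4), row.names = FALSE)
  invisible(x)
}

#' @export
plot.dmt_monitor <- function(x, ...) {
  s <- x$summary
  graphics::par(mfrow = c(1, 2))
  graphics::plot(s$cut, s$delta_out, type = "b", pch = 19,
                 xlab = "data cut", ylab = "C-index change vs reference",
                 main = "discrimination over accrual", ...)
  graphics::lines(s$cut, s$delta_in, type = "b", lty = 2)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topleft", c("out-of-sample", "in-sample"),
                   lty = c(1, 2), bty = "n")
  graphics::plot(s$cut, s$median_span, type = "b", pch = 19,
                 xlab = "data cut", ylab = "median 90% interval span",
                 main = "coefficient stability", ...)
  invisible(x)
}
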