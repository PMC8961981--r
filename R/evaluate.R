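#' Per-patient therapy ranking matrix
#'
#' Event-free probability of every catalogue DMT for every row of a switch
#' table, from thinned posterior draws — the bulk form of
#' [prob_event_free()] used to rank therapies for thousands of patients at
#' once.
#'
#' @param fit A `dmt_fit`.
#' @param table A `switch_table`.
#' @param horizon_months Ranking horizon.
#' @param thin Maximum number of posterior draws used.
#' @return `n x K` matrix of event-free probabilities (columns in catalogue
#'   order).
#' @export
ranking_matrix <- function(fit, table, horizon_months = 48, thin = 400) {
  K <- nrow(fit$catalogue)
  out <- matrix(NA_real_, nrow(table), K,
                dimnames = list(NULL, fit$catalogue$dmt_id))
  S <- nrow(fit$draws)
  keep <- if (S > thin) round(seq(1, S, length.out = thin)) else seq_len(S)
  f2 <- fit
  f2$draws <- fit$draws[keep, , drop = FALSE]
  for (d in fit$catalogue$dmt_id) {
    eta <- linpred_draws(f2, table, dmt = d)
    out[, d] <- colMeans(event_free_draws(f2, eta, horizon_months))
  }
  out
}

#' Label which patients followed the ranking
#'
#' For each row, ranks all catalogue DMTs by the patient's own predicted
#' event-free probability at the index date and labels the row as
#' "followed" when the actually assigned DMT falls in the scenario's rank
#' set: the single highest-ranked therapy (`top1`), one of the two highest
#' (`top2`), or one of the two lowest (`bottom2`).
#'
#' @param table A `switch_table`.
#' @param fit The `dmt_fit` for the scenario's outcome.
#' @param scenario `"top1"`, `"top2"` or `"bottom2"`.
#' @param horizon_months Ranking horizon.
#' @return Logical vector, one element per row.
#' @export
label_adherence <- function(table, fit, scenario = c("top1", "top2", "bottom2"),
                            horizon_months = 48) {
  scenario <- match.arg(scenario)
  P <- ranking_matrix(fit, table, horizon_months)
  K <- ncol(P)
  if (K < 2 || (scenario != "top1" && K < 4)) {
    stop_input("catalogue too small for scenario %s", scenario)
  }
  assigned <- match(table$assigned_dmt, colnames(P))
  vapply(seq_len(nrow(P)), function(i) {
    o <- order(-P[i, ], seq_len(K))  # ties: catalogue order
    rk <- match(assigned[i], o)
    switch(scenario, top1 = rk == 1, top2 = rk <= 2, bottom2 = rk >= K - 1)
  }, TRUE)
}

#' Propensity-score weights for adherence comparisons
#'
#' Models the probability of belonging to the "followed the recommendation"
#' group from the ten baseline covariates (logistic regression; the previous
#' therapy enters as indicator terms with rare levels under 1% prevalence
#' collapsed to `"other"`), then forms stabilised average-treatment-effect
#' weights, Hajek-normalised to mean 1 within each group and trimmed at the
#' configured percentiles. Balance is reported as
#' the standardised mean difference of every covariate term before and
#' after weighting. A 1:1 nearest-neighbour matching alternative (on the
#' logit propensity, without replacement) is available via `method`.
#'
#' @param table A `switch_table`.
#' @param followed Logical adherence labels, as from [label_adherence()].
#' @param covariates Covariate names (default: the ten predictors).
#' @param trim Weight-trimming percentiles.
#' @param method `"weighting"` (default) or `"matching"`.
#' @return List with `weights`, `propensity`, `balance` (`data.frame` of
#'   SMDs), `model`.
#' @export
propensity_weights <- function(table, followed,
                               covariates = predictor_names(),
                               trim = c(0.01, 0.99),
                               method = c("weighting", "matching")) {
  method <- match.arg(method)
  followed <- as.logical(followed)
  if (!any(followed) || all(followed)) {
    stop_input("both adherence groups must be non-empty (followed: %d of %d)",
               sum(followed), length(followed))
  }
  df <- table[, covariates, drop = FALSE]
  if ("current_dmt" %in% covariates) {
    tabd <- table(df$current_dmt) / nrow(df)
    rare <- names(tabd)[tabd < 0.01]
    df$current_dmt <- ifelse(df$current_dmt %in% rare, "other", df$current_dmt)
    df$current_dmt <- factor(df$current_dmt)
  }
  if ("sex" %in% covariates) df$sex <- factor(df$sex)
  df$.followed <- followed
  ps_fit <- stats::glm(.followed ~ ., data = df, family = stats::binomial())
  ps <- stats::fitted(ps_fit)
  if (any(ps > 1 - 1e-8) || any(ps < 1e-8)) {
    stop_input(paste("perfect or near-perfect separation in the propensity",
                     "model; inspect overlap or strengthen trimming"))
  }
  pbar <- mean(followed)
  w <- ifelse(followed, pbar / ps, (1 - pbar) / (1 - ps))
  # Hajek normalisation: mean weight exactly 1 within each group
  w[followed] <- w[followed] / mean(w[followed])
  w[!followed] <- w[!followed] / mean(w[!followed])
  if (method == "weighting") {
    lim <- stats::quantile(w, trim, names = FALSE)
    w_trim <- pmin(pmax(w, lim[1]), lim[2])
  } else {
    w_trim <- match_weights(ps, followed)
  }

  M <- stats::model.matrix(ps_fit)[, -1, drop = FALSE]
  smd <- function(wt) {
    apply(M, 2, function(x) {
      m1 <- stats::weighted.mean(x[followed], wt[followed])
      m0 <- stats::weighted.mean(x[!followed], wt[!followed])
      sp <- sqrt((stats::var(x[followed]) + stats::var(x[!followed])) / 2)
      if (sp < 1e-12) 0 else (m1 - m0) / sp
    })
  }
  bal <- data.frame(covariate = colnames(M),
                    smd_unweighted = smd(rep(1, nrow(M))),
                    smd_weighted = smd(w_trim), row.names = NULL)
  list(weights = w_trim, weights_untrimmed = w, propensity = ps,
       balance = bal, model = ps_fit, method = method)
}

# Greedy 1:1 nearest-neighbour matching on the logit propensity.
match_weights <- function(ps, followed) {
  lp <- stats::qlogis(ps)
  treated <- which(followed)
  control <- which(!followed)
  w <- numeric(length(ps))
  used <- logical(length(control))
  for (i in treated[order(lp[treated], decreasing = TRUE)]) {
    d <- abs(lp[control] - lp[i])
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j])) {
      used[j] <- TRUE
      w[i] <- 1
      w[control[j]] <- 1
    }
  }
  w
}

#' Survey-weighted outcome model for one adherence scenario
#'
#' The effect of following the recommendation on the outcome scale: a
#' weighted negative-binomial regression of the relapse count on the
#' adherence indicator with a log-exposure offset, or a weighted binomial
#' regression of the 3mCDP indicator on the adherence indicator. The slope
#' coefficient is the adherence effect (negative = lower disease activity
#' in the followed group); its p-value uses the design-robust sandwich
#' variance, two-sided.
#'
#' @param table A `switch_table`.
#' @param weights Positive weights from [propensity_weights()].
#' @param followed Logical adherence labels.
#' @param outcome `"relapse"` or `"cdp"`.
#' @return Object of class `scenario_result`: `slope`, `se`, `p_value`,
#'   `n_followed`, `n_other`, `flag` (`NA` unless degenerate).
#' @export
weighted_outcome_model <- function(table, weights, followed,
                                   outcome = c("relapse", "cdp")) {
  outcome <- match.arg(outcome)
  keep <- weights > 0
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop_input("weights must be finite and non-negative")
  }
  d <- data.frame(followed = as.logical(followed)[keep], w = weights[keep])
  res <- list(slope = NA_real_, se = NA_real_, p_value = NA_real_,
              n_followed = sum(followed), n_other = sum(!followed),
              flag = NA_character_, outcome = outcome)
  fit <- if (outcome == "relapse") {
    d$y <- table$relapse_count[keep]
    d$off <- log(table$exposure_months[keep])
    if (all(d$y == 0)) NULL else {
      tryCatch(
        suppressWarnings(MASS::glm.nb(y ~ followed + offset(off),
                                      data = d, weights = w)),
        error = function(e) tryCatch(
          suppressWarnings(stats::glm(y ~ followed + offset(off), data = d,
                                      weights = w,
                                      family = stats::quasipoisson())),
          error = function(e) NULL)
      )
    }
  } else {
    d$y <- as.numeric(table$cdp_event[keep])
    if (all(d$y == 0) || all(d$y == 1)) NULL else {
      tryCatch(
        suppressWarnings(stats::glm(y ~ followed, data = d, weights = w,
                                    family = stats::quasibinomial())),
        error = function(e) NULL)
    }
  }
  if (is.null(fit)) {
    res$flag <- "degenerate outcome: no model fitted"
    return(structure(res, class = "scenario_result"))
  }
  slope <- stats::coef(fit)[["followedTRUE"]]
  vc <- tryCatch(sandwich::vcovHC(fit, type = "HC0"),
                 error = function(e) stats::vcov(fit))
  se <- sqrt(vc["followedTRUE", "followedTRUE"])
  res$slope <- slope
  res$se <- se
  res$p_value <- 2 * stats::pnorm(-abs(slope / se))
  if (isFALSE(fit$converged)) res$flag <- "outcome model did not converge"
  structure(res, class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result %s> slope %.4f (SE %.4f), p = %.4g, n = %d vs %d%s\n",
              x$outcome, x$slope, x$se, x$p_value, x$n_followed, x$n_other,
              if (is.na(x$flag)) "" else paste0(" [", x$flag, "]")))
  invisible(x)
}

#' The full adherence-scenario grid
#'
#' Runs the three recommendation-adherence scenarios (highest-ranked
#' therapy, one of the two highest, one of the two lowest) for both
#' outcomes: label adherence from the patient-specific ranking, balance the
#' groups by stabilised propensity weighting on the ten covariates, and
#' estimate the adherence effect with the survey-weighted outcome model.
#' Group-level outcome summaries (annualised relapse rate, 3mCDP fraction)
#' accompany each cell.
#'
#' @param table A `switch_table`.
#' @param fit_relapse,fit_cdp Fitted outcome models.
#' @param horizon_months Ranking horizon.
#' @param covariates Propensity covariates.
#' @return `data.frame` of class `dmt_scenarios`, one row per scenario x
#'   outcome: `scenario`, `outcome`, `slope`, `se`, `p_value`,
#'   `n_followed`, `n_other`, `max_smd_weighted`, `outcome_followed`,
#'   `outcome_other` (ARR or event fraction per group).
#' @export
run_scenarios <- function(table, fit_relapse, fit_cdp, horizon_months = 48,
                          covariates = predictor_names()) {
  grid <- expand.grid(scenario = c("top1", "top2", "bottom2"),
                      outcome = c("relapse", "cdp"), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- grid$scenario[i]
    oc <- grid$outcome[i]
    fit <- if (oc == "relapse") fit_relapse else fit_cdp
    fol <- label_adherence(table, fit, sc, horizon_months)
    pw <- propensity_weights(table, fol, covariates)
    wm <- weighted_outcome_model(table, pw$weights, fol, oc)
    if (oc == "relapse") {
      arr <- 12 * table$relapse_count / table$exposure_months
      g1 <- mean(arr[fol]); g0 <- mean(arr[!fol])
    } else {
      g1 <- mean(table$cdp_event[fol]); g0 <- mean(table$cdp_event[!fol])
    }
    data.frame(scenario = sc, outcome = oc, slope = wm$slope, se = wm$se,
               p_value = wm$p_value, n_followed = wm$n_followed,
               n_other = wm$n_other,
               max_smd_unweighted = max(abs(pw$balance$smd_unweighted)),
               max_smd_weighted = max(abs(pw$balance$smd_weighted)),
               outcome_followed = g1, outcome_other = g0,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("dmt_scenarios", "data.frame"))
}

#' RCT arm specification
#'
#' Describes one published trial arm for external comparison: the DMT, the
#' trial duration, the published proportion of event-free patients, and the
#' inclusion filters expressed over the predictor fields. Published numbers
#' are user-supplied configuration, not bundled claims.
#'
#' @param trial Trial name.
#' @param dmt Arm DMT id.
#' @param outcome `"relapse"` or `"cdp"`.
#' @param duration_months Trial duration.
#' @param published_event_free Published proportion event-free in `(0, 1)`.
#' @param published_ci90 Optional published 90% interval (length 2).
#' @param filters Named list of inclusion filters; supported names:
#'   `edss_min`, `edss_max`, `age_min`, `age_max`, `min_relapses_12m`,
#'   `max_time_since_diagnosis`, `require_previous_dmt`.
#' @return Object of class `rct_arm_spec`.
#' @export
rct_arm_spec <- function(trial, dmt, outcome = c("relapse", "cdp"),
                         duration_months, published_event_free,
                         published_ci90 = NULL, filters = list()) {
  outcome <- match.arg(outcome)
  stopifnot(published_event_free > 0, published_event_free < 1,
            duration_months >= 0)
  known <- c("edss_min", "edss_max", "age_min", "age_max", "min_relapses_12m",
             "max_time_since_diagnosis", "require_previous_dmt")
  bad <- setdiff(names(filters), known)
  if (length(bad)) stop_input("unknown filter(s): %s", paste(bad, collapse = ", "))
  structure(list(trial = trial, dmt = dmt, outcome = outcome,
                 duration_months = duration_months,
                 published_event_free = published_event_free,
                 published_ci90 = published_ci90, filters = filters),
            class = "rct_arm_spec")
}

#' @rdname rct_arm_spec
#' @param path JSON file holding a list of arm objects.
#' @export
read_rct_arms <- function(path) {
  xs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(xs, function(x) {
    rct_arm_spec(x$trial, x$dmt, x$outcome, x$duration_months,
                 x$published_event_free, x$published_ci90 %||% NULL,
                 x$filters %||% list())
  })
}

apply_arm_filters <- function(table, filters) {
  keep <- rep(TRUE, nrow(table))
  checks <- list(
    edss_min = function(t, v) t$edss >= v,
    edss_max = function(t, v) t$edss <= v,
    age_min = function(t, v) t$age >= v,
    age_max = function(t, v) t$age <= v,
    min_relapses_12m = function(t, v) t$relapses_last_12m >= v,
    max_time_since_diagnosis = function(t, v) t$time_since_diagnosis <= v,
    require_previous_dmt = function(t, v) !v | t$n_previous_dmts >= 1
  )
  for (nm in names(filters)) {
    new <- keep & checks[[nm]](table, filters[[nm]])
    if (!any(new)) {
      stop_input("filter '%s' excludes every patient (had %d left)",
                 nm, sum(keep))
    }
    keep <- new
  }
  keep
}

#' Compare model predictions with a published trial arm
#'
#' Selects registry rows matching the arm's inclusion filters, predicts each
#' patient's probability of staying event-free over the trial duration under
#' the arm's DMT, and compares the cohort mean (with its 90% credible
#' interval from the posterior draws of the cohort mean) to the published
#' proportion. A difference of 10% or more raises the discrepancy flag.
#' The baseline-comparability table reports means and SDs of the continuous
#' covariates and frequencies of the categorical ones for the selected
#' cohort.
#'
#' @param table A `switch_table`.
#' @param fit The `dmt_fit` matching the arm's outcome.
#' @param arm An [rct_arm_spec()].
#' @param thin Maximum posterior draws used.
#' @return Object of class `rct_comparison`.
#' @export
compare_with_rct <- function(table, fit, arm, thin = 1000) {
  stopifnot(inherits(arm, "rct_arm_spec"))
  if (fit$spec$outcome != arm$outcome) {
    stop_input("fit is for outcome '%s' but the arm specifies '%s'",
               fit$spec$outcome, arm$outcome)
  }
  assert_in_catalogue(arm$dmt, fit$catalogue)
  keep <- apply_arm_filters(table, arm$filters)
  sub <- table[keep, , drop = FALSE]
  S <- nrow(fit$draws)
  kp <- if (S > thin) round(seq(1, S, length.out = thin)) else seq_len(S)
  f2 <- fit
  f2$draws <- fit$draws[kp, , drop = FALSE]
  eta <- linpred_draws(f2, sub, dmt = arm$dmt)
  p <- event_free_draws(f2, eta, arm$duration_months)  # S x n
  cohort_mean_draws <- rowMeans(p)
  predicted <- mean(cohort_mean_draws)
  ci90 <- stats::quantile(cohort_mean_draws, c(0.05, 0.95), names = FALSE)
  per_patient <- colMeans(p)

  cont <- CONT_PREDICTORS
  baseline <- rbind(
    data.frame(covariate = cont,
               statistic = "mean (sd)",
               value = vapply(cont, function(v)
                 sprintf("%.2f (%.2f)", mean(sub[[v]]), stats::sd(sub[[v]])), "")),
    data.frame(covariate = c("sex=female", "any_previous_second_line"),
               statistic = "fraction",
               value = c(sprintf("%.3f", mean(sub$sex == "female")),
                         sprintf("%.3f", mean(sub$any_previous_second_line))))
  )
  structure(
    list(trial = arm$trial, dmt = arm$dmt, outcome = arm$outcome,
         n = nrow(sub), predicted = predicted, ci90 = ci90,
         published = arm$published_event_free,
         difference = predicted - arm$published_event_free,
         flagged = abs(predicted - arm$published_event_free) >= 0.10,
         prediction_quantiles = stats::quantile(per_patient, c(0.05, 0.95),
                                                names = FALSE),
         baseline = baseline),
    class = "rct_comparison"
  )
}

#' @export
print.rct_comparison <- function(x, ...) {
  cat(sprintf("<rct_comparison %s / %s (%s-free)>\n", x$trial, x$dmt, x$outcome))
  cat(sprintf("  n = %d; predicted %.3f [%.3f, %.3f]; published %.3f; diff %+.3f%s\n",
              x$n, x$predicted, x$ci90[1], x$ci90[2], x$published,
              x$difference, if (x$flagged) "  ** >= 10% discrepancy **" else ""))
  invisible(x)
}
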