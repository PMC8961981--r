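#' Specification of the synthetic registry generator
#'
#' Bundles every ground-truth parameter of the synthetic cohort: cohort size,
#' DMT catalogue, true covariate effects on the log relapse rate and on the
#' log 3mCDP hazard (natural units, centred at typical covariate values),
#' true per-DMT effects for both outcomes, the negative-binomial dispersion,
#' the confounded therapy-assignment model, the exposure distribution and the
#' master seed. A fixed seed yields a byte-identical cohort; patient `i` is
#' generated from its own deterministic sub-stream, so enlarging `n_patients`
#' never changes already-generated patients (registry accrual is a superset).
#'
#' Default sizes emulate the registry the models were developed on
#' (about 3,100 eligible switch patients, roughly 70% female, baseline
#' annualised relapse rate around 0.4, 3mCDP risk around 12% over two
#' years); see the methods vignette for the rationale behind each value.
#'
#' @param n_patients Number of patients.
#' @param catalogue A [dmt_catalogue()].
#' @param relapse_effects Named list: `intercept` (log relapse rate per month
#'   for the reference patient), `slopes` (named vector, natural units),
#'   `dmt` (named log rate multipliers, one per catalogue DMT).
#' @param cdp_effects Same shape for the log 3mCDP hazard per month.
#' @param dispersion NB dispersion `r` (variance `mu + mu^2/r`).
#' @param assignment Confounded DMT assignment: `strength` scales how much
#'   sicker patients are channelled to second-line therapy (0 = randomised).
#' @param exposure `meanlog`, `sdlog`, `min`, `max` of the log-normal
#'   follow-up duration in months.
#' @param frac_high_edss,frac_early Fractions of deliberately ineligible
#'   patients (EDSS > 6 at index; switch < 6 months after diagnosis).
#' @param relapse_cap_months Coding cap for time since last relapse.
#' @param seed Master seed.
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(n_patients = 3119,
                           catalogue = default_dmt_catalogue(),
                           relapse_effects = default_relapse_effects(catalogue),
                           cdp_effects = default_cdp_effects(catalogue),
                           dispersion = 1.5,
                           assignment = list(strength = 0.7),
                           exposure = list(meanlog = log(24), sdlog = 0.5,
                                           min = 6, max = 60),
                           frac_high_edss = 0.02, frac_early = 0.02,
                           relapse_cap_months = 120,
                           seed = 20260101) {
  stopifnot(dispersion > 0, n_patients >= 1)
  for (eff in list(relapse_effects, cdp_effects)) {
    stopifnot(setequal(names(eff$dmt), catalogue$dmt_id))
    stopifnot(all(names(eff$slopes) %in% setdiff(predictor_names(),
                                                 "current_dmt")))
  }
  structure(
    list(n_patients = as.integer(n_patients), catalogue = catalogue,
         relapse_effects = relapse_effects, cdp_effects = cdp_effects,
         dispersion = dispersion, assignment = assignment,
         exposure = exposure, frac_high_edss = frac_high_edss,
         frac_early = frac_early, relapse_cap_months = relapse_cap_months,
         seed = as.integer(seed)),
    class = "generator_spec"
  )
}

# Covariate centres used by the generator's linear predictors, so that the
# stated intercepts are rates for a "typical" switching patient.
generator_centers <- function() {
  c(age = 38, edss = 2.5, current_dmt_duration = 18, n_previous_dmts = 1.7,
    time_since_diagnosis = 84, relapses_last_12m = 0.6,
    time_since_last_relapse = 24)
}

#' @rdname generator_spec
#' @export
default_relapse_effects <- function(catalogue = default_dmt_catalogue()) {
  dmt <- c(interferon_beta = 0, glatiramer_acetate = 0.05,
           dimethyl_fumarate = -0.15, teriflunomide = -0.05,
           fingolimod = -0.35, natalizumab = -0.60,
           ocrelizumab = -0.70, cladribine = -0.45)
  missing <- setdiff(catalogue$dmt_id, names(dmt))
  dmt <- c(dmt[intersect(names(dmt), catalogue$dmt_id)],
           stats::setNames(rep(0, length(missing)), missing))
  list(
    intercept = log(0.4 / 12),  # baseline ARR 0.4/year for the reference DMT
    slopes = c(age = -0.010, sex = 0.05, edss = 0.10,
               current_dmt_duration = -0.004, n_previous_dmts = 0.10,
               any_previous_second_line = 0.15, time_since_diagnosis = -0.002,
               relapses_last_12m = 0.25, time_since_last_relapse = -0.004),
    dmt = dmt[catalogue$dmt_id]
  )
}

#' @rdname generator_spec
#' @export
default_cdp_effects <- function(catalogue = default_dmt_catalogue()) {
  dmt <- c(interferon_beta = 0, glatiramer_acetate = 0.05,
           dimethyl_fumarate = -0.10, teriflunomide = -0.02,
           fingolimod = -0.25, natalizumab = -0.40,
           ocrelizumab = -0.50, cladribine = -0.30)
  missing <- setdiff(catalogue$dmt_id, names(dmt))
  dmt <- c(dmt[intersect(names(dmt), catalogue$dmt_id)],
           stats::setNames(rep(0, length(missing)), missing))
  list(
    intercept = log(0.0053),  # ~12% 3mCDP risk over 24 months at reference
    slopes = c(age = 0.005, sex = 0.10, edss = 0.12,
               current_dmt_duration = 0, n_previous_dmts = 0.08,
               any_previous_second_line = 0.10, time_since_diagnosis = 0.001,
               relapses_last_12m = 0.10, time_since_last_relapse = -0.002),
    dmt = dmt[catalogue$dmt_id]
  )
}

# Natural-unit linear predictor (without exposure); vectorised over the rows
# of `cov` (a list for one patient or a data.frame) and over `dmt`.
truth_linpred <- function(eff, cov, dmt) {
  ctr <- generator_centers()
  s <- eff$slopes
  lp <- eff$intercept + unname(eff$dmt[dmt])
  for (nm in names(s)) {
    x <- switch(nm,
      sex = as.numeric(cov$sex == "male"),
      any_previous_second_line = as.numeric(cov$any_previous_second_line),
      cov[[nm]] - ctr[[nm]]
    )
    lp <- lp + s[[nm]] * x
  }
  lp
}

#' Generate a synthetic registry cohort
#'
#' Simulates `spec$n_patients` longitudinal patient records around a single
#' DMT-switch index date each: demographics, 1-3 historical therapy episodes,
#' pre-index relapse history and EDSS assessments, a confounded assignment of
#' the new DMT (sicker patients are channelled towards second-line
#' therapies), and post-switch outcomes drawn from the ground-truth models —
#' relapse counts from a negative binomial with exposure offset (relapse
#' dates placed as a homogeneous Poisson process conditioned on the drawn
#' count) and 3mCDP events from a constant-hazard model, embedded in the
#' EDSS trajectory as a sustained confirmed step so that [derive_3mcdp()]
#' recovers every generated event exactly. EDSS recording starts shortly
#' before the index switch (late registry entry), so earlier switches in the
#' history fail eligibility screening — each patient contributes exactly one
#' modelling row unless deliberately generated ineligible.
#'
#' @param spec A [generator_spec()].
#' @return List of [patient_record()]s with attribute `truth` (the
#'   generating [generator_spec()]).
#' @export
generate_cohort <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  cohort <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    cohort[[i]] <- with_seed(fork_seed(spec$seed, i),
                             sim_patient(spec, i))
  }
  names(cohort) <- vapply(cohort, `[[`, "", "patient_id")
  attr(cohort, "truth") <- spec
  cohort
}

# Simulate one patient; assumes the RNG is already seeded for this patient.
sim_patient <- function(spec, i) {
  cat_ids <- spec$catalogue$dmt_id
  index_date <- as.Date("2016-01-01") + sample.int(1095, 1) - 1

  u <- stats::runif(1)
  kind <- if (u < spec$frac_high_edss) "high_edss"
          else if (u < spec$frac_high_edss + spec$frac_early) "early" else "ok"

  age <- min(max(stats::rnorm(1, 38, 9), 18), 70)
  sex <- if (stats::runif(1) < 0.7) "female" else "male"
  edss <- min(max(round(stats::rgamma(1, shape = 2.8, scale = 0.9) * 2) / 2, 0), 6)
  if (kind == "high_edss") edss <- sample(seq(6.5, 8, by = 0.5), 1)

  tsd <- if (kind == "early") stats::runif(1, 1, 5.5) else
    min(max(stats::rlnorm(1, log(84), 0.6), 12), 280)
  diagnosis_date <- add_months(index_date, -tsd)

  # therapy history: n_prev previous episodes then the current one ending at
  # index; all history episodes last >= 6 months
  n_prev <- if (kind == "early") 0L else sample(0:2, 1, prob = c(0.45, 0.4, 0.15))
  n_hist <- n_prev + 1L
  max_hist <- max(tsd - 1, 6.5)
  durs <- stats::rlnorm(n_hist, log(18), 0.5)
  durs <- pmax(durs, 6)
  durs <- durs * min(1, max_hist / sum(durs))
  durs <- pmax(durs, if (kind == "early") 0.9 else 4)
  hist_dmts <- sample(cat_ids, n_hist, replace = FALSE)
  bounds <- index_date
  for (d in rev(durs)) bounds <- c(add_months(bounds[1], -d), bounds)
  hist_eps <- fast_df(dmt_id = hist_dmts,
                      start_date = bounds[seq_len(n_hist)],
                      end_date = bounds[seq_len(n_hist) + 1L])
  current_dmt <- hist_dmts[n_hist]

  # pre-index relapse history
  n12 <- stats::rpois(1, 0.7)
  rel_dates <- as.Date(character())
  if (n12 > 0) {
    rel_dates <- add_months(index_date, -stats::runif(n12, 0.3, 11.9))
  }
  if (stats::runif(1) < 0.6) {
    rel_dates <- c(rel_dates, add_months(index_date, -stats::runif(1, 13, 70)))
  }

  # registry entry: EDSS recorded from ~3 months before the index switch
  pre_edss <- fast_df(date = c(add_months(index_date, -2.8), index_date - 7),
                      score = c(edss, edss))

  # covariates as extract_predictors will see them (for the truth model)
  prev_dmts <- unique(hist_dmts[seq_len(n_prev)])
  past <- rel_dates[rel_dates <= index_date]
  cov <- list(
    age = age, sex = sex, edss = edss,
    current_dmt_duration = months_between(hist_eps$start_date[n_hist], index_date),
    n_previous_dmts = length(prev_dmts),
    any_previous_second_line = length(prev_dmts) > 0 &&
      any(is_second_line(prev_dmts, spec$catalogue)),
    time_since_diagnosis = tsd,
    relapses_last_12m = sum(past > add_months(index_date, -12)),
    time_since_last_relapse = if (length(past))
      min(months_between(max(past), index_date), spec$relapse_cap_months)
    else spec$relapse_cap_months
  )

  # confounded assignment: severity channels towards second-line DMTs
  sev <- (cov$edss - 2.5) / 1.5 + (cov$relapses_last_12m - 0.6) / 0.8
  align <- ifelse(spec$catalogue$line == 2L, 1, -1)
  util <- spec$assignment$strength * align * sev +
    -log(-log(stats::runif(length(cat_ids))))  # Gumbel noise -> softmax draw
  assigned <- cat_ids[which.max(util)]

  # follow-up on the new DMT
  ex <- spec$exposure
  exposure <- min(max(stats::rlnorm(1, ex$meanlog, ex$sdlog), ex$min), ex$max)
  new_ep <- fast_df(dmt_id = assigned, start_date = index_date,
                    end_date = add_months(index_date, exposure))

  # outcomes from the ground truth
  mu <- exposure * exp(truth_linpred(spec$relapse_effects, cov, assigned))
  n_rel <- stats::rnbinom(1, size = spec$dispersion, mu = mu)
  if (n_rel > 0) {
    post_rel <- index_date + sort(stats::runif(n_rel, 1,
                                               exposure * DAYS_PER_MONTH - 1))
    rel_dates <- c(rel_dates, as.Date(round(as.numeric(post_rel)),
                                      origin = "1970-01-01"))
  }

  lam <- exp(truth_linpred(spec$cdp_effects, cov, assigned))
  p_evt <- 1 - exp(-lam * exposure)
  evt <- stats::runif(1) < p_evt
  fu <- sim_edss_followup(edss, index_date, exposure, evt, lam)
  ed_dates <- c(pre_edss$date, fu$date)
  ed_order <- order(ed_dates)
  edss_df <- fast_df(date = ed_dates[ed_order],
                     score = c(pre_edss$score, fu$score)[ed_order])
  eps <- fast_df(dmt_id = c(hist_eps$dmt_id, new_ep$dmt_id),
                 start_date = c(hist_eps$start_date, new_ep$start_date),
                 end_date = c(hist_eps$end_date, new_ep$end_date))

  new_patient_record(
    patient_id = sprintf("P%06d", i), sex = sex,
    birth_year = as.integer(as.POSIXlt(index_date)$year + 1900 - floor(age)),
    diagnosis_date = diagnosis_date,
    episodes = eps,
    relapses = sort(rel_dates), edss = edss_df
  )
}

# Quarterly EDSS follow-up embedding (or safely avoiding) a confirmed
# progression step. Reference score `ref` is the last pre-index assessment.
sim_edss_followup <- function(ref, index_date, exposure, event, hazard) {
  step <- if (ref <= 5.5) 1.0 else 0.5
  times <- seq(3, exposure + 6, by = 3)  # months after index
  lo <- max(0, ref - 1)
  hi <- ref + step - 0.5
  sc <- numeric(length(times))
  s <- ref
  for (k in seq_along(times)) {
    s <- min(max(s + sample(c(-0.5, 0, 0.5), 1, prob = c(0.15, 0.7, 0.15)), lo), hi)
    sc[k] <- s
  }
  dates <- add_months(index_date, times)
  if (event) {
    # event time under the constant hazard, conditional on the event
    u <- stats::runif(1)
    t_star <- -log(1 - u * (1 - exp(-hazard * exposure))) / hazard
    t_star <- min(t_star, exposure - 0.5)
    at <- times >= t_star
    sc[at] <- pmax(sc[at], ref + step)
    # ensure a visit at the provoking increase and a confirming one >= 90 days
    # later exists on the quarterly grid (grid extends 6 months past exposure)
    dates <- c(dates, add_months(index_date, t_star))
    sc <- c(sc, ref + step)
  }
  fast_df(date = dates, score = sc)
}

#' Accruing cohort series for robustness monitoring
#'
#' Emulates quarterly registry growth: cut `k` contains the first
#' `round(n0 * (1 + growth)^(k-1))` patients of one master cohort, so each
#' cut is a strict superset of the previous one (patients are only ever
#' added) and all shared patients are identical across cuts. Default growth
#' is 1.3% per cut, the registry's observed quarterly accrual rate.
#'
#' @param spec A [generator_spec()] describing the first cut.
#' @param n_cuts Number of data cuts (>= 1).
#' @param growth_per_cut Fractional growth per cut.
#' @return List of cohorts of increasing size.
#' @export
generate_growth_series <- function(spec, n_cuts, growth_per_cut = 0.013) {
  stopifnot(n_cuts >= 1, growth_per_cut > 0)
  sizes <- round(spec$n_patients * (1 + growth_per_cut)^(seq_len(n_cuts) - 1))
  big <- spec
  big$n_patients <- max(sizes)
  master <- generate_cohort(big)
  lapply(sizes, function(n) {
    cut <- master[seq_len(n)]
    attr(cut, "truth") <- spec
    cut
  })
}

#' Synthetic adherence data for evaluating the weighting machinery
#'
#' Generates switch-table rows where the "followed the recommendation" label
#' is confounded with the ten baseline covariates (sicker patients are more
#' likely to follow) and the outcomes carry a known adherence effect:
#' `delta_log_rr` on the log relapse rate and `delta_log_or` on the log
#' 3mCDP hazard. This isolates the propensity-weighting estimator from the
#' Bayesian ranking pipeline, so its bias and type-I calibration can be
#' measured against an exact truth.
#'
#' @param n Number of rows.
#' @param delta_log_rr,delta_log_or True adherence effects (0 = null).
#' @param confounding Strength of the covariate effect on following.
#' @param spec A [generator_spec()] for covariate distributions and truth.
#' @param seed Seed.
#' @param base_table Optional pre-built `switch_table` whose covariates are
#'   reused (labels and outcomes are redrawn) — lets replicate loops share
#'   one simulated cohort.
#' @return A `switch_table` with extra logical column `followed`.
#' @export
generate_adherence_table <- function(n, delta_log_rr = -0.5,
                                     delta_log_or = -0.45,
                                     confounding = 0.8,
                                     spec = generator_spec(), seed = 1,
                                     base_table = NULL) {
  tab <- base_table
  if (is.null(tab)) {
    cohort <- with_seed(seed, {
      s <- spec
      s$n_patients <- n
      s$seed <- fork_seed(seed, 777)
      s$frac_high_edss <- 0
      s$frac_early <- 0
      generate_cohort(s)
    })
    tab <- build_switch_table(cohort, spec$catalogue, spec$relapse_cap_months)
  }
  with_seed(fork_seed(seed, 778), {
    sev <- scale(tab$edss)[, 1] + scale(tab$relapses_last_12m)[, 1] +
      0.5 * scale(tab$age)[, 1]
    p_follow <- stats::plogis(-0.2 + confounding * sev)
    followed <- stats::runif(nrow(tab)) < p_follow
    # redraw outcomes with the adherence effect layered on the ground truth
    lp_r <- truth_linpred(spec$relapse_effects, tab, tab$assigned_dmt)
    mu <- tab$exposure_months * exp(lp_r + delta_log_rr * followed)
    tab$relapse_count <- stats::rnbinom(nrow(tab), size = spec$dispersion, mu = mu)
    lp_c <- truth_linpred(spec$cdp_effects, tab, tab$assigned_dmt)
    lam <- exp(lp_c + delta_log_or * followed)
    tab$cdp_event <- stats::runif(nrow(tab)) < 1 - exp(-lam * tab$exposure_months)
    tab$followed <- followed
    attr(tab, "truth") <- list(delta_log_rr = delta_log_rr,
                               delta_log_or = delta_log_or)
    tab
  })
}

#' Compare a fit against the generator's ground truth
#'
#' Maps the generator's natural-unit true coefficients into the fitted
#' model's parameterisation and summarises recovery: slopes are multiplied
#' by the training SD frozen in the fit (binary predictors are untouched),
#' DMT effects are compared as contrasts against their across-DMT mean
#' (the identified combination once the intercept absorbs the overall
#' level), previous-therapy dummies have true effect zero, and the relapse
#' model's log dispersion is compared directly.
#'
#' @param fit A [fit_outcome_model()] result.
#' @param spec The [generator_spec()] the training cohort came from.
#' @return `data.frame`: `coefficient`, `truth`, `post_mean`, `post_sd`,
#'   `lower90`, `upper90`, `covered` (does the 90% interval contain the
#'   truth), `z` (standardised error).
#' @export
coefficient_recovery <- function(fit, spec) {
  eff <- if (fit$spec$outcome == "relapse") spec$relapse_effects else
    spec$cdp_effects
  cn <- fit$constants
  d <- fit$draws
  idx <- fit$idx

  draws <- list()
  truth <- c()
  for (v in CONT_PREDICTORS) {
    draws[[v]] <- d[, v]
    truth[v] <- (eff$slopes[[v]] %||% 0) * cn$scale[[v]]
  }
  draws[["sex_male"]] <- d[, "sex_male"]
  truth["sex_male"] <- eff$slopes[["sex"]] %||% 0
  draws[["any_previous_second_line"]] <- d[, "any_previous_second_line"]
  truth["any_previous_second_line"] <- eff$slopes[["any_previous_second_line"]] %||% 0
  for (l in setdiff(cn$prev_levels, cn$prev_ref)) {
    nm <- paste0("prev_", l)
    draws[[nm]] <- d[, nm]
    truth[nm] <- 0
  }
  # DMT effects as contrasts vs the across-DMT mean
  a <- d[, idx$alpha, drop = FALSE]
  a_c <- a - rowMeans(a)
  t_c <- eff$dmt - mean(eff$dmt)
  for (j in seq_along(cn$dmt_levels)) {
    nm <- paste0("dmt_", cn$dmt_levels[j])
    draws[[nm]] <- a_c[, j]
    truth[nm] <- t_c[[cn$dmt_levels[j]]]
  }
  if (!is.null(idx$log_r)) {
    draws[["log_dispersion"]] <- d[, "log_dispersion"]
    truth["log_dispersion"] <- log(spec$dispersion)
  }

  rows <- lapply(names(draws), function(nm) {
    x <- draws[[nm]]
    q <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
    m <- mean(x)
    s <- stats::sd(x)
    data.frame(coefficient = nm, truth = unname(truth[nm]), post_mean = m,
               post_sd = s, lower90 = q[1], upper90 = q[2],
               covered = truth[nm] >= q[1] & truth[nm] <= q[2],
               z = (m - truth[nm]) / s, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
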