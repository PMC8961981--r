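#' Patient record
#'
#' In-memory representation of one patient's longitudinal registry history:
#' demographics, ordered therapy episodes, relapse dates and EDSS assessments.
#'
#' Invariants enforced at construction: episodes are sorted by start date and
#' non-overlapping (an episode covers the half-open interval
#' `[start_date, end_date)`); EDSS scores lie on the 0.5 grid within
#' \[0, 10\]; relapse and assessment dates are valid calendar dates. Relapses
#' may predate the recorded diagnosis date.
#'
#' @param patient_id Opaque identifier string.
#' @param sex `"female"` or `"male"`.
#' @param birth_year Integer year of birth.
#' @param diagnosis_date Date of the RRMS diagnosis.
#' @param episodes `data.frame` with columns `dmt_id`, `start_date`,
#'   `end_date` (`NA` for an ongoing episode).
#' @param relapses Vector of relapse onset dates.
#' @param edss `data.frame` with columns `date`, `score`.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, sex, birth_year, diagnosis_date,
                           episodes, relapses = as.Date(character()),
                           edss = data.frame(date = as.Date(character()),
                                             score = numeric())) {
  if (is.null(diagnosis_date) || length(diagnosis_date) != 1 ||
      is.na(diagnosis_date)) {
    stop_input("patient %s: missing diagnosis_date", patient_id)
  }
  if (!sex %in% c("female", "male")) {
    stop_input("patient %s: sex must be 'female' or 'male'", patient_id)
  }
  episodes <- as.data.frame(episodes)
  stopifnot(all(c("dmt_id", "start_date", "end_date") %in% names(episodes)))
  episodes$start_date <- as.Date(episodes$start_date)
  episodes$end_date <- as.Date(episodes$end_date)
  if (nrow(episodes) > 1) {
    o <- order(episodes$start_date)
    episodes <- episodes[o, , drop = FALSE]
    closed_end <- episodes$end_date[-nrow(episodes)]
    if (anyNA(closed_end) ||
        any(closed_end > episodes$start_date[-1])) {
      stop_input("patient %s: overlapping or open non-final episodes", patient_id)
    }
  }
  if (nrow(episodes)) {
    closed <- !is.na(episodes$end_date)
    if (any(episodes$start_date[closed] >= episodes$end_date[closed])) {
      stop_input("patient %s: episode start must precede end", patient_id)
    }
  }
  edss <- as.data.frame(edss)
  stopifnot(all(c("date", "score") %in% names(edss)))
  edss$date <- as.Date(edss$date)
  edss$score <- as.numeric(edss$score)
  validate_edss_scores(edss$score, patient_id)
  edss <- edss[order(edss$date), , drop = FALSE]
  relapses <- sort(as.Date(relapses))

  structure(
    list(patient_id = as.character(patient_id), sex = sex,
         birth_year = as.integer(birth_year),
         diagnosis_date = as.Date(diagnosis_date),
         episodes = episodes, relapses = relapses, edss = edss),
    class = "patient_record"
  )
}

# Trusted constructor for internally generated records: the synthetic
# generator guarantees every invariant by construction (sorted, closed,
# non-overlapping episodes; grid EDSS; sorted dates), so the per-patient
# validation and coercion of patient_record() is skipped. Round-trip and
# invariant tests cover the generator's output through the public API.
new_patient_record <- function(patient_id, sex, birth_year, diagnosis_date,
                               episodes, relapses, edss) {
  structure(
    list(patient_id = patient_id, sex = sex, birth_year = birth_year,
         diagnosis_date = diagnosis_date, episodes = episodes,
         relapses = relapses, edss = edss),
    class = "patient_record"
  )
}

validate_edss_scores <- function(score, patient_id = "?") {
  bad <- !is.na(score) & (score < 0 | score > 10 |
                            abs(score * 2 - round(score * 2)) > 1e-9)
  if (any(bad)) {
    stop_input("patient %s: EDSS score %s not a multiple of 0.5 in [0, 10]",
               patient_id, paste(unique(score[bad]), collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record %s> %s, born %d, diagnosed %s\n", x$patient_id,
              x$sex, x$birth_year, format(x$diagnosis_date)))
  cat(sprintf("  %d episode(s), %d relapse(s), %d EDSS assessment(s)\n",
              nrow(x$episodes), length(x$relapses), nrow(x$edss)))
  invisible(x)
}

# Most recent EDSS assessment at or before `date`; NULL if none.
last_edss_before <- function(p, date) {
  d <- p$edss$date
  i <- which(d <= date)
  if (!length(i)) return(NULL)
  j <- i[length(i)]
  list(date = d[j], score = p$edss$score[j])
}

# The therapy episode being taken (and possibly discontinued) at `date`:
# latest episode starting strictly before `date` whose end is at/after `date`
# (open episodes qualify). At a switch boundary the outgoing episode
# (end == date) is the current one; the incoming episode is not yet "current".
current_episode_index <- function(p, date) {
  ep <- p$episodes
  cand <- which(ep$start_date < date &
                  (is.na(ep$end_date) | ep$end_date >= date))
  if (!length(cand)) return(NA_integer_)
  cand[which.max(as.numeric(ep$start_date[cand]))]
}

#' Eligibility screening at an index date
#'
#' A patient is eligible for prediction at a DMT-switch index date when at
#' least 6 months have passed since the RRMS diagnosis, an EDSS assessment
#' exists at or before the index date, and the most recent such assessment is
#' at most 6.0 (the scale is too non-linear above 6 for the models to apply).
#' Both boundaries are inclusive: exactly 6 months since diagnosis and an
#' EDSS of exactly 6.0 are accepted.
#'
#' @param p A [patient_record()].
#' @param index_date The prospective switch date.
#' @return A list with `eligible` (logical) and `reason` (`NA` if eligible).
#' @export
check_eligibility <- function(p, index_date) {
  stopifnot(inherits(p, "patient_record"))
  index_date <- as.Date(index_date)
  msd <- months_between(p$diagnosis_date, index_date)
  if (msd < 6) {
    return(list(eligible = FALSE,
                reason = sprintf("< 6 months since diagnosis (%.1f)", msd)))
  }
  e <- last_edss_before(p, index_date)
  if (is.null(e)) {
    return(list(eligible = FALSE, reason = "no EDSS assessment before index"))
  }
  if (e$score > 6.0) {
    return(list(eligible = FALSE, reason = sprintf("EDSS > 6 (%.1f)", e$score)))
  }
  list(eligible = TRUE, reason = NA_character_)
}

#' Extract the predictor vector at a DMT-switch index date
#'
#' Computes the ten predictors the outcome models use, as of `index_date`:
#' age, sex, current EDSS, the therapy being discontinued and its duration,
#' the number of distinct previous DMT substances, whether any previous DMT
#' was second-line, time since diagnosis, the relapse count in the last 12
#' months (half-open window `(index - 12m, index]`) and the time since the
#' most recent relapse (capped at `relapse_cap_months` for patients whose
#' last relapse is older or who never relapsed).
#'
#' @inheritParams check_eligibility
#' @param catalogue A [dmt_catalogue()] supplying the line classification.
#' @param relapse_cap_months Cap (and never-relapsed coding) for
#'   `time_since_last_relapse`, in months.
#' @return A one-row `data.frame` with the predictor columns.
#' @export
extract_predictors <- function(p, index_date, catalogue = default_dmt_catalogue(),
                               relapse_cap_months = 120) {
  stopifnot(inherits(p, "patient_record"))
  index_date <- as.Date(index_date)
  ci <- current_episode_index(p, index_date)
  if (is.na(ci)) stop_input("patient %s: no current DMT at index", p$patient_id)
  cur_dmt <- p$episodes$dmt_id[ci]
  cur_start <- p$episodes$start_date[ci]
  assert_in_catalogue(cur_dmt, catalogue)
  prev_dmts <- unique(p$episodes$dmt_id[seq_len(ci - 1L)])
  e <- last_edss_before(p, index_date)
  if (is.null(e)) stop_input("patient %s: no EDSS before index", p$patient_id)

  window_start <- add_months(index_date, -12)
  n12 <- sum(p$relapses > window_start & p$relapses <= index_date)
  past <- p$relapses[p$relapses <= index_date]
  tslr <- if (length(past)) {
    min(months_between(max(past), index_date), relapse_cap_months)
  } else {
    relapse_cap_months
  }

  lt <- as.POSIXlt(index_date)
  fast_df(
    age = (lt$year + 1900 - p$birth_year) + lt$yday / 365.25,
    sex = p$sex,
    edss = e$score,
    current_dmt = cur_dmt,
    current_dmt_duration = months_between(cur_start, index_date),
    n_previous_dmts = length(prev_dmts),
    any_previous_second_line = any(is_second_line(prev_dmts, catalogue)),
    time_since_diagnosis = months_between(p$diagnosis_date, index_date),
    relapses_last_12m = n12,
    time_since_last_relapse = tslr
  )
}

#' Derive 3-month confirmed disability progression
#'
#' 3mCDP is an EDSS increase versus the reference assessment (the most recent
#' one at or before the index date) that is confirmed by a later assessment.
#' The required step is 1.0 point when the reference EDSS is <= 5.5 and 0.5
#' point above that. A provoking increase within the horizon counts as an
#' event when a subsequent assessment at least 90 days later still meets the
#' increase and no assessment in between drops below it (sustained
#' progression); the confirming assessment itself may fall after the horizon.
#' This step rule is the standard MS-trial definition, stated here as an
#' explicit modelling assumption.
#'
#' @inheritParams check_eligibility
#' @param horizon_months Follow-up window after the index date, in months.
#' @return List with `event` (logical), `event_date` (provoking increase date
#'   or `NA`), and `censored` (`TRUE` when no post-index assessment exists).
#' @export
derive_3mcdp <- function(p, index_date, horizon_months = Inf) {
  stopifnot(inherits(p, "patient_record"))
  index_date <- as.Date(index_date)
  ref <- last_edss_before(p, index_date)
  if (is.null(ref)) stop_input("patient %s: no reference EDSS at index", p$patient_id)
  step <- if (ref$score <= 5.5) 1.0 else 0.5
  thr <- ref$score + step

  sel <- p$edss$date > index_date
  if (!any(sel)) {
    return(list(event = FALSE, event_date = as.Date(NA), censored = TRUE))
  }
  pd <- p$edss$date[sel]
  ps <- p$edss$score[sel]
  horizon_end <- if (is.finite(horizon_months)) {
    add_months(index_date, horizon_months)
  } else {
    max(pd)
  }

  cand <- which(ps >= thr & pd <= horizon_end)
  for (i in cand) {
    later <- which(pd >= pd[i] + 90)
    if (!length(later)) next
    j <- later[1]
    if (all(ps[i:j] >= thr)) {
      return(list(event = TRUE, event_date = pd[i], censored = FALSE))
    }
  }
  list(event = FALSE, event_date = as.Date(NA), censored = FALSE)
}

#' Build the model training table from a cohort
#'
#' Walks every patient's therapy history, treats the start of each episode
#' after the first as a DMT switch, screens it with [check_eligibility()],
#' and emits one row per eligible switch: the predictor vector at the index
#' date, the newly assigned DMT, the observed exposure on it (episode length
#' censored at the last recorded assessment/relapse and at
#' `max_exposure_months`), the relapse count during exposure and the 3mCDP
#' indicator. Patients or switches failing eligibility are skipped, never
#' fatal.
#'
#' @param cohort List of [patient_record()]s.
#' @param catalogue A [dmt_catalogue()].
#' @param relapse_cap_months See [extract_predictors()].
#' @param max_exposure_months Exposure censoring cap, in months.
#' @param verbose Emit a message per skipped switch.
#' @return A `data.frame` of class `switch_table`; attribute `skipped` counts
#'   rejected switches by reason.
#' @export
build_switch_table <- function(cohort, catalogue = default_dmt_catalogue(),
                               relapse_cap_months = 120,
                               max_exposure_months = 72, verbose = FALSE) {
  acc <- list()
  skipped <- character()
  for (k in seq_along(cohort)) {
    p <- cohort[[k]]
    if (nrow(p$episodes) < 2) next
    last_obs <- suppressWarnings(max(c(p$edss$date, p$relapses)))
    for (j in 2:nrow(p$episodes)) {
      index_date <- p$episodes$start_date[j]
      elig <- check_eligibility(p, index_date)
      if (!elig$eligible) {
        skipped <- c(skipped, elig$reason)
        if (verbose) message(sprintf("skip %s @ %s: %s", p$patient_id,
                                     format(index_date), elig$reason))
        next
      }
      x <- tryCatch(
        extract_predictors(p, index_date, catalogue, relapse_cap_months),
        error = function(e) NULL
      )
      if (is.null(x)) {
        skipped <- c(skipped, "predictor extraction failed")
        next
      }
      ep_end <- p$episodes$end_date[j]
      end_obs <- if (is.na(ep_end)) last_obs else min(ep_end, last_obs)
      exposure <- min(months_between(index_date, end_obs), max_exposure_months)
      if (!is.finite(exposure) || exposure <= 0) {
        skipped <- c(skipped, "non-positive exposure")
        next
      }
      exp_end <- add_months(index_date, exposure)
      cdp <- derive_3mcdp(p, index_date, exposure)
      acc[[length(acc) + 1L]] <- c(
        list(patient_id = p$patient_id, index_date = index_date),
        as.list(x),
        list(assigned_dmt = p$episodes$dmt_id[j],
             exposure_months = exposure,
             relapse_count = sum(p$relapses > index_date &
                                   p$relapses <= exp_end),
             cdp_event = cdp$event, cdp_censored = cdp$censored)
      )
    }
  }
  tab <- if (length(acc)) {
    cols <- names(acc[[1]])
    out <- lapply(cols, function(cn) {
      v <- lapply(acc, `[[`, cn)
      if (cn == "index_date") as.Date(unlist(v), origin = "1970-01-01")
      else unlist(v)
    })
    names(out) <- cols
    do.call(fast_df, out)
  } else {
    empty_switch_table()
  }
  rownames(tab) <- NULL
  structure(tab, class = c("switch_table", "data.frame"),
            skipped = table(skipped))
}

empty_switch_table <- function() {
  data.frame(patient_id = character(), index_date = as.Date(character()),
             age = numeric(), sex = character(), edss = numeric(),
             current_dmt = character(), current_dmt_duration = numeric(),
             n_previous_dmts = integer(), any_previous_second_line = logical(),
             time_since_diagnosis = numeric(), relapses_last_12m = integer(),
             time_since_last_relapse = numeric(), assigned_dmt = character(),
             exposure_months = numeric(), relapse_count = integer(),
             cdp_event = logical(), cdp_censored = logical(),
             stringsAsFactors = FALSE)
}

# Names of the ten predictors, in canonical order.
predictor_names <- function() {
  c("age", "sex", "edss", "current_dmt", "current_dmt_duration",
    "n_previous_dmts", "any_previous_second_line", "time_since_diagnosis",
    "relapses_last_12m", "time_since_last_relapse")
}
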