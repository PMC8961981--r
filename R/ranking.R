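#' Rank therapies for an individual patient
#'
#' Computes, for every DMT in the catalogue, the probability of staying
#' relapse-free and free of 3mCDP over the horizon, and orders each outcome
#' column by decreasing posterior-mean probability (the point probability,
#' as in the tool's display; ranking on the lower interval bound is
#' available via `rank_on`). Ties are broken by the narrower 90% interval,
#' then by catalogue order. Preference-excluded DMTs keep their computed
#' probability and interval but carry no rank (they are "shaded"): excluding
#' a therapy never changes any other therapy's numbers.
#'
#' @param fit_relapse,fit_cdp Fitted models from [fit_outcome_model()] for
#'   the two outcomes (either may be `NULL` to rank a single outcome).
#' @param x One predictor row.
#' @param horizon_months Horizon in months (clinical range 24-72).
#' @param exclude Character vector of DMT ids excluded by patient/physician
#'   preference, or a named character vector `dmt = reason`.
#' @param rank_on `"probability"` (default) or `"lower90"`.
#' @return Object of class `dmt_ranking`: a list of per-outcome data.frames
#'   with columns `dmt_id`, `probability`, `lower90`, `upper90`, `excluded`,
#'   `reason`, `rank`.
#' @export
rank_therapies <- function(fit_relapse, fit_cdp, x, horizon_months = 48,
                           exclude = character(),
                           rank_on = c("probability", "lower90")) {
  rank_on <- match.arg(rank_on)
  fits <- list(relapse_free = fit_relapse, cdp_free = fit_cdp)
  fits <- fits[!vapply(fits, is.null, TRUE)]
  if (!length(fits)) stop_input("at least one fitted model is required")
  catalogue <- fits[[1]]$catalogue
  if (!nrow(catalogue)) stop_input("empty DMT catalogue")
  for (f in fits) {
    if (!identical(f$catalogue$dmt_id, catalogue$dmt_id)) {
      stop_input("fits do not share the same DMT catalogue")
    }
  }
  reasons <- if (!is.null(names(exclude)) && any(nzchar(names(exclude)))) {
    stats::setNames(unname(exclude), names(exclude))
  } else {
    stats::setNames(rep("excluded by preference", length(exclude)), exclude)
  }
  assert_in_catalogue(names(reasons), catalogue)

  tables <- lapply(fits, function(f) {
    res <- lapply(catalogue$dmt_id, function(d) {
      p <- prob_event_free(f, x, d, horizon_months)
      data.frame(dmt_id = d, probability = p$probability,
                 lower90 = p$ci90[1], upper90 = p$ci90[2],
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, res)
    tab$excluded <- tab$dmt_id %in% names(reasons)
    tab$reason <- ifelse(tab$excluded, reasons[tab$dmt_id], NA_character_)
    key <- if (rank_on == "probability") tab$probability else tab$lower90
    width <- tab$upper90 - tab$lower90
    o <- order(-key, width, match(tab$dmt_id, catalogue$dmt_id))
    tab <- tab[o, , drop = FALSE]
    tab$rank <- NA_integer_
    tab$rank[!tab$excluded] <- seq_len(sum(!tab$excluded))
    rownames(tab) <- NULL
    tab
  })
  structure(list(outcomes = tables, horizon_months = horizon_months,
                 rank_on = rank_on, patient = x),
            class = "dmt_ranking")
}

#' @export
print.dmt_ranking <- function(x, ...) {
  cat(sprintf("<dmt_ranking> horizon %g months\n", x$horizon_months))
  for (nm in names(x$outcomes)) {
    cat(sprintf("\n%s:\n", nm))
    t <- x$outcomes[[nm]]
    for (i in seq_len(nrow(t))) {
      cat(sprintf("  %s %-20s %s  [%.2f, %.2f]%s\n",
                  if (is.na(t$rank[i])) " -" else sprintf("%2d", t$rank[i]),
                  t$dmt_id[i], natural_frequency(t$probability[i]),
                  t$lower90[i], t$upper90[i],
                  if (t$excluded[i]) paste0("  (", t$reason[i], ")") else ""))
    }
  }
  invisible(x)
}

#' Natural-frequency rendering of a probability
#'
#' Probabilities are communicated as "N of 100 patients like you", rounded
#' half-up to an integer per 100.
#'
#' @param p Probability in `[0, 1]`.
#' @return Character string.
#' @export
natural_frequency <- function(p) {
  sprintf("%d of 100", round_half_up(p * 100))
}

#' Structured ranking report
#'
#' Serialises a [rank_therapies()] result — probabilities, natural
#' frequencies, 90% intervals, horizon, rank and exclusion shading, plus the
#' per-predictor contribution panel from [explain_prediction()] — as a JSON
#' string (and optionally to a file). Byte-stable for identical inputs.
#'
#' @param ranking A `dmt_ranking`.
#' @param fit_relapse,fit_cdp The fits used to build it (for the
#'   contribution panel; either may be `NULL`).
#' @param path Optional output file.
#' @return The JSON string, invisibly if `path` is given.
#' @export
render_report <- function(ranking, fit_relapse = NULL, fit_cdp = NULL,
                          path = NULL) {
  stopifnot(inherits(ranking, "dmt_ranking"))
  fits <- list(relapse_free = fit_relapse, cdp_free = fit_cdp)
  out <- list(horizon_months = ranking$horizon_months,
              rank_on = ranking$rank_on,
              outcomes = list())
  for (nm in names(ranking$outcomes)) {
    t <- ranking$outcomes[[nm]]
    t$natural_frequency <- natural_frequency(t$probability)
    t$probability <- round(t$probability, 6)
    t$lower90 <- round(t$lower90, 6)
    t$upper90 <- round(t$upper90, 6)
    out$outcomes[[nm]] <- t
    f <- fits[[nm]]
    if (!is.null(f)) {
      top <- t$dmt_id[which(t$rank == 1)]
      expl <- explain_prediction(f, ranking$patient, top)
      expl$contribution <- round(expl$contribution, 6)
      expl$percentile <- round(expl$percentile, 1)
      out$outcomes[[nm]] <- list(ranking = t, top_dmt = top,
                                 contributions = expl)
    }
  }
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, na = "null",
                           pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}
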