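# Design-matrix construction for the outcome models.
#
# Continuous predictors are standardised by training mean/SD; binary
# predictors enter as 0/1; the previous (discontinued) therapy enters as
# one-hot dummies against the most frequent training category. The
# standardisation constants and category levels are frozen at fit time and
# re-applied verbatim to any new data, so predictions never depend on the
# composition of the prediction set.

CONT_PREDICTORS <- c("age", "edss", "current_dmt_duration", "n_previous_dmts",
                     "time_since_diagnosis", "relapses_last_12m",
                     "time_since_last_relapse")

design_constants <- function(table, catalogue) {
  center <- vapply(CONT_PREDICTORS, function(v) mean(table[[v]]), 0)
  scale <- vapply(CONT_PREDICTORS, function(v) stats::sd(table[[v]]), 0)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  lev <- names(sort(table(table$current_dmt), decreasing = TRUE))
  lev <- c(lev, setdiff(catalogue$dmt_id, lev))
  # training-distribution quantiles for the percentile panel of
  # explain_prediction()
  qgrid <- seq(0, 1, by = 0.01)
  quantiles <- lapply(CONT_PREDICTORS, function(v)
    stats::quantile(table[[v]], qgrid, names = FALSE, type = 7))
  names(quantiles) <- CONT_PREDICTORS
  list(center = center, scale = scale,
       prev_levels = lev, prev_ref = lev[1],
       dmt_levels = catalogue$dmt_id,
       quantiles = quantiles,
       frac_male = mean(table$sex == "male"),
       frac_prev_second = mean(table$any_previous_second_line))
}

# Rows of `table` -> list(X = fixed-effect matrix, dmt = assigned-DMT index).
build_design <- function(table, constants) {
  n <- nrow(table)
  Xc <- sapply(CONT_PREDICTORS, function(v)
    (table[[v]] - constants$center[[v]]) / constants$scale[[v]])
  if (n == 1) Xc <- matrix(Xc, nrow = 1, dimnames = list(NULL, CONT_PREDICTORS))
  Xb <- cbind(sex_male = as.numeric(table$sex == "male"),
              any_previous_second_line = as.numeric(table$any_previous_second_line))
  other <- setdiff(constants$prev_levels, constants$prev_ref)
  Xd <- sapply(other, function(l) as.numeric(table$current_dmt == l))
  if (n == 1) Xd <- matrix(Xd, nrow = 1, dimnames = list(NULL, other))
  colnames(Xd) <- paste0("prev_", other)
  X <- cbind(Xc, Xb, Xd)

  unknown <- setdiff(unique(table$assigned_dmt), constants$dmt_levels)
  if (length(unknown)) {
    stop_input("unknown assigned DMT id(s): %s; catalogue has: %s",
               paste(unknown, collapse = ", "),
               paste(constants$dmt_levels, collapse = ", "))
  }
  list(X = X, dmt = match(table$assigned_dmt, constants$dmt_levels))
}

check_collinear <- function(X) {
  qr_ <- qr(cbind(1, X))
  if (qr_$rank < ncol(X) + 1) {
    keep <- qr_$pivot[seq_len(qr_$rank)]
    dropped <- setdiff(seq_len(ncol(X) + 1), keep) - 1L
    stop_input("degenerate design: collinear column(s): %s",
               paste(colnames(X)[dropped], collapse = ", "))
  }
  invisible(TRUE)
}
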