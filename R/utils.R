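#' @keywords internal
#' @useDynLib dmtrank, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# One month in days. All durations in the package are real-valued months.
DAYS_PER_MONTH <- 30.4375

#' Convert a day difference to months
#'
#' The package measures every duration (time since diagnosis, therapy
#' duration, exposure, time since last relapse, prediction horizon) in
#' real-valued months of 30.4375 days.
#'
#' @param from,to `Date` vectors.
#' @return Numeric vector of month differences (`to - from`).
#' @export
months_between <- function(from, to) {
  (as.numeric(as.Date(to)) - as.numeric(as.Date(from))) / DAYS_PER_MONTH
}

#' @rdname months_between
#' @param d `Date` vector.
#' @param m Numeric vector of months to add.
#' @return `add_months()`: a `Date` vector shifted by `m` months.
#' @export
add_months <- function(d, m) {
  as.Date(d) + round(m * DAYS_PER_MONTH)
}

# Deterministically fork a 32-bit seed for a sub-stream. Knuth multiplicative
# hashing keeps forks well separated for consecutive indices.
fork_seed <- function(seed, index) {
  s <- (as.double(seed) * 2654435761 + as.double(index) * 40503) %% 2147483647
  as.integer(s)
}

# Run `expr` under a local RNG state seeded with `seed`, restoring the caller's
# RNG afterwards so package functions never disturb the user's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stop_input <- function(fmt, ...) {
  stop(structure(
    class = c("dmtrank_input_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Round-half-up to integer (natural-frequency rendering; base round() is
# round-half-even which would turn 0.735 -> 73 or 74 platform-independently
# but 73.5 -> 74 is the documented rule here).
round_half_up <- function(x) floor(x + 0.5)

# Fast internal data.frame constructor for hot paths (no checks, no copies).
fast_df <- function(...) {
  l <- list(...)
  n <- length(l[[1]])
  structure(l, class = "data.frame", row.names = c(NA_integer_, -n))
}
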