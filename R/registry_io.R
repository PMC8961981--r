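#' Read and write cohorts in the registry CSV dialect
#'
#' A cohort is exchanged as four UTF-8 CSV files in one directory, keyed by
#' `patient_id`, with all dates ISO-8601 (`YYYY-MM-DD`):
#'
#' * `patients.csv` — `patient_id, sex, birth_year, diagnosis_date`
#' * `episodes.csv` — `patient_id, dmt_id, start_date, end_date` (empty
#'   `end_date` for an ongoing episode)
#' * `relapses.csv` — `patient_id, date`
#' * `edss.csv` — `patient_id, date, score`
#'
#' Reading validates every record through [patient_record()]; malformed rows
#' are reported with their file and line number, and missing mandatory
#' columns are a hard failure. Writing then reading reproduces the cohort
#' exactly (dates at day precision, scores on the 0.5 grid).
#'
#' @param dir Directory holding (or receiving) the four files.
#' @return `read_registry()`: a list of [patient_record()]s.
#' @export
read_registry <- function(dir) {
  read_one <- function(file, cols) {
    path <- file.path(dir, file)
    if (!file.exists(path)) stop_input("missing registry file: %s", path)
    x <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", encoding = "UTF-8")
    miss <- setdiff(cols, names(x))
    if (length(miss)) {
      stop_input("%s: missing mandatory column(s): %s", file,
                 paste(miss, collapse = ", "))
    }
    x
  }
  pts <- read_one("patients.csv", c("patient_id", "sex", "birth_year",
                                    "diagnosis_date"))
  eps <- read_one("episodes.csv", c("patient_id", "dmt_id", "start_date",
                                    "end_date"))
  rel <- read_one("relapses.csv", c("patient_id", "date"))
  eds <- read_one("edss.csv", c("patient_id", "date", "score"))

  parse_date <- function(s, file) {
    d <- as.Date(s, format = "%Y-%m-%d")
    bad <- which(is.na(d) & !is.na(s) & nzchar(s))
    if (length(bad)) {
      stop_input("%s line %d: invalid date '%s'", file, bad[1] + 1L, s[bad[1]])
    }
    d
  }
  eps$start_date <- parse_date(eps$start_date, "episodes.csv")
  eps$end_date <- parse_date(eps$end_date, "episodes.csv")
  rel$date <- parse_date(rel$date, "relapses.csv")
  eds$date <- parse_date(eds$date, "edss.csv")
  eds$score <- as.numeric(eds$score)
  pts$diagnosis_date <- parse_date(pts$diagnosis_date, "patients.csv")

  eps_by <- split(eps, eps$patient_id)
  rel_by <- split(rel, rel$patient_id)
  eds_by <- split(eds, eds$patient_id)

  cohort <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    id <- pts$patient_id[i]
    e <- eps_by[[id]]
    cohort[[i]] <- tryCatch(
      patient_record(
        patient_id = id, sex = pts$sex[i],
        birth_year = as.integer(pts$birth_year[i]),
        diagnosis_date = pts$diagnosis_date[i],
        episodes = if (is.null(e)) {
          data.frame(dmt_id = character(), start_date = as.Date(character()),
                     end_date = as.Date(character()))
        } else {
          e[c("dmt_id", "start_date", "end_date")]
        },
        relapses = if (is.null(rel_by[[id]])) as.Date(character()) else
          rel_by[[id]]$date,
        edss = if (is.null(eds_by[[id]])) {
          data.frame(date = as.Date(character()), score = numeric())
        } else {
          eds_by[[id]][c("date", "score")]
        }
      ),
      error = function(err) {
        stop_input("patients.csv line %d (patient %s): %s", i + 1L, id,
                   conditionMessage(err))
      }
    )
  }
  names(cohort) <- pts$patient_id
  cohort
}

#' @rdname read_registry
#' @param cohort List of [patient_record()]s.
#' @return `write_registry()`: `dir`, invisibly.
#' @export
write_registry <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))
  pts <- data.frame(
    patient_id = vapply(cohort, `[[`, "", "patient_id"),
    sex = vapply(cohort, `[[`, "", "sex"),
    birth_year = vapply(cohort, `[[`, 0L, "birth_year"),
    diagnosis_date = vapply(cohort, function(p) fmt(p$diagnosis_date), ""),
    stringsAsFactors = FALSE
  )
  bind <- function(f) do.call(rbind, lapply(cohort, f))
  eps <- bind(function(p) {
    if (!nrow(p$episodes)) return(NULL)
    data.frame(patient_id = p$patient_id, dmt_id = p$episodes$dmt_id,
               start_date = fmt(p$episodes$start_date),
               end_date = fmt(p$episodes$end_date), stringsAsFactors = FALSE)
  })
  rel <- bind(function(p) {
    if (!length(p$relapses)) return(NULL)
    data.frame(patient_id = p$patient_id, date = fmt(p$relapses),
               stringsAsFactors = FALSE)
  })
  eds <- bind(function(p) {
    if (!nrow(p$edss)) return(NULL)
    data.frame(patient_id = p$patient_id, date = fmt(p$edss$date),
               score = p$edss$score, stringsAsFactors = FALSE)
  })
  empty <- function(...) data.frame(..., stringsAsFactors = FALSE)[0, , drop = FALSE]
  utils::write.csv(pts, file.path(dir, "patients.csv"), row.names = FALSE)
  utils::write.csv(eps %||% empty(patient_id = "", dmt_id = "", start_date = "",
                                  end_date = ""),
                   file.path(dir, "episodes.csv"), row.names = FALSE)
  utils::write.csv(rel %||% empty(patient_id = "", date = ""),
                   file.path(dir, "relapses.csv"), row.names = FALSE)
  utils::write.csv(eds %||% empty(patient_id = "", date = "", score = 0),
                   file.path(dir, "edss.csv"), row.names = FALSE)
  invisible(dir)
}
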