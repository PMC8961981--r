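#' DMT catalogue
#'
#' The catalogue of disease-modifying therapies the models know about. Each
#' entry carries an identifier, a display name and its treatment-line
#' classification (`1` for platform/first-line, `2` for second-line /
#' high-efficacy therapies). The line classification feeds the
#' "any previous second-line therapy" predictor; it is deliberately a
#' user-editable configuration, not a hard-coded clinical claim.
#'
#' @param dmt_id Character vector of identifiers.
#' @param name Display names (defaults to `dmt_id`).
#' @param line Integer vector of 1s and 2s.
#' @return A `data.frame` of class `dmt_catalogue` with columns
#'   `dmt_id`, `name`, `line`.
#' @export
#' @examples
#' default_dmt_catalogue()
dmt_catalogue <- function(dmt_id, name = dmt_id, line) {
  stopifnot(length(dmt_id) == length(line), length(dmt_id) == length(name))
  if (anyDuplicated(dmt_id)) stop_input("duplicate dmt_id in catalogue")
  if (!all(line %in% c(1L, 2L))) stop_input("catalogue line must be 1 or 2")
  structure(
    data.frame(dmt_id = as.character(dmt_id), name = as.character(name),
               line = as.integer(line), stringsAsFactors = FALSE),
    class = c("dmt_catalogue", "data.frame")
  )
}

#' @rdname dmt_catalogue
#' @export
default_dmt_catalogue <- function() {
  dmt_catalogue(
    dmt_id = c("interferon_beta", "glatiramer_acetate", "dimethyl_fumarate",
               "teriflunomide", "fingolimod", "natalizumab",
               "ocrelizumab", "cladribine"),
    name = c("Interferon beta", "Glatiramer acetate", "Dimethyl fumarate",
             "Teriflunomide", "Fingolimod", "Natalizumab",
             "Ocrelizumab", "Cladribine"),
    line = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L)
  )
}

#' @rdname dmt_catalogue
#' @param path File path for the JSON representation.
#' @export
read_dmt_catalogue <- function(path) {
  x <- jsonlite::fromJSON(path)
  dmt_catalogue(x$dmt_id, x$name %||% x$dmt_id, x$line)
}

#' @rdname dmt_catalogue
#' @param catalogue A `dmt_catalogue`.
#' @export
write_dmt_catalogue <- function(catalogue, path) {
  stopifnot(inherits(catalogue, "dmt_catalogue"))
  jsonlite::write_json(unclass(catalogue)[c("dmt_id", "name", "line")], path,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

assert_in_catalogue <- function(dmt_id, catalogue) {
  bad <- setdiff(dmt_id, catalogue$dmt_id)
  if (length(bad)) {
    stop_input("unknown DMT id(s): %s; catalogue has: %s",
               paste(bad, collapse = ", "),
               paste(catalogue$dmt_id, collapse = ", "))
  }
  invisible(TRUE)
}

is_second_line <- function(dmt_id, catalogue) {
  catalogue$line[match(dmt_id, catalogue$dmt_id)] == 2L
}
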