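# Embryo record tables on disk.
#
# One CSV row per embryo: state, 0-based transition frames, stage
# intervals in minutes, trace variance. Missing transitions are empty
# cells, never sentinel numbers. An optional nested per-frame fluorescence
# table is serialized as a JSON-encoded cell so a single file round-trips.

.RECORD_COLS <- c("incubator", "state", "bean_frame", "twitch_frame",
                  "hatch_frame", "bean_to_twitch_min", "twitch_to_hatch_min",
                  "trace_variance", "error")

#' Write embryo records to CSV
#'
#' @param records Record tibble as produced by [phenotype_chip()] (an empty
#'   tibble yields a header-only file). A list-column `fluorescence` of
#'   per-frame measurement tibbles, when present, is serialized as JSON in
#'   a `fluorescence_json` column.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_records <- function(records, path) {
  out <- records
  if ("fluorescence" %in% names(out)) {
    out$fluorescence_json <- vapply(out$fluorescence, function(m) {
      if (is.null(m)) NA_character_
      else as.character(jsonlite::toJSON(m, digits = NA, na = "null"))
    }, "")
    out$fluorescence <- NULL
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read embryo records from CSV
#'
#' Inverse of [save_records()]: re-reading reproduces the records,
#' including the nested fluorescence measurements when present.
#'
#' @param path CSV path.
#' @return Record tibble.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  spec <- readr::cols(
    incubator = readr::col_integer(),
    state = readr::col_character(),
    bean_frame = readr::col_integer(),
    twitch_frame = readr::col_integer(),
    hatch_frame = readr::col_integer(),
    bean_to_twitch_min = readr::col_double(),
    twitch_to_hatch_min = readr::col_double(),
    trace_variance = readr::col_double(),
    error = readr::col_character(),
    .default = readr::col_character())
  x <- readr::read_csv(path, col_types = spec, na = "",
                       progress = FALSE, show_col_types = FALSE)
  attr(x, "spec") <- NULL
  attr(x, "problems") <- NULL
  class(x) <- c("tbl_df", "tbl", "data.frame")
  if ("fluorescence_json" %in% names(x)) {
    x$fluorescence <- lapply(x$fluorescence_json, function(s) {
      if (is.na(s)) return(NULL)
      m <- tibble::as_tibble(jsonlite::fromJSON(s))
      if ("flag" %in% names(m)) m$flag <- as.character(m$flag)
      m
    })
    x$fluorescence_json <- NULL
  }
  x
}
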