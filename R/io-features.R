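#' Write a feature table to CSV
#'
#' RFC-4180 CSV with a header row: the five metadata columns `subject_id`,
#' `trial_id`, `window_index`, `valence_label`, `arousal_label`, then one
#' column per feature named `<channel>_<band>_<stat>` in the canonical
#' channel-major order. An empty (zero-row) table writes a header-only CSV.
#'
#' @param records Feature tibble from [assemble_features()] (or the same
#'   shape).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(records, path) {
  records <- tibble::as_tibble(records)
  meta <- c("subject_id", "trial_id", "window_index",
            "valence_label", "arousal_label")
  if (!all(meta %in% names(records))) {
    abort_validation(sprintf(
      "feature table lacks metadata column(s): %s",
      paste(setdiff(meta, names(records)), collapse = ", ")
    ))
  }
  fc <- feature_cols(records)
  if (nrow(records) > 0L && !all(vapply(records[fc], is.numeric, logical(1)))) {
    abort_validation("all feature columns must be numeric")
  }
  records <- records[, c(meta, fc)]
  readr::write_csv(records, path)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Path to the CSV.
#' @return A tibble in the same column layout.
#' @export
read_feature_table <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      trial_id = readr::col_integer(),
      window_index = readr::col_integer(),
      valence_label = readr::col_character(),
      arousal_label = readr::col_character(),
      .default = readr::col_double()
    )
  )
}
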