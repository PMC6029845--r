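# Lightweight persistence helpers: array containers as RDS, tabular outputs
# as CSV, records as JSON.

#' Write / read an epochs or RDM container
#'
#' Containers (epochs, RDM time courses, generalization maps) persist via
#' R's native serialization; tabular exports use CSV and records JSON.
#'
#' @param x Object to persist.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_container <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) readRDS(path)

#' Write a trial-rejection report
#'
#' @param rejected Data frame from [reject_by_peak_to_peak()].
#' @param threshold The threshold used.
#' @param path Destination JSON file.
#' @return `path`, invisibly.
#' @export
write_rejection_report <- function(rejected, threshold, path) {
  jsonlite::write_json(list(threshold = threshold, rejected = rejected),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a fusion series (or any time-series data frame) as CSV
#'
#' @param x Data frame.
#' @param path Destination CSV file.
#' @return `path`, invisibly.
#' @export
export_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Export MDS coordinates as CSV
#'
#' @param coords Matrix from [mds_embed()].
#' @param path Destination CSV file.
#' @return `path`, invisibly.
#' @export
export_mds <- function(coords, path) {
  df <- data.frame(condition_id = rownames(coords), coords,
                   row.names = NULL, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
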