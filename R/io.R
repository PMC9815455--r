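# Dataset serialization.  The native container is a single RDS file
# holding the recording, the ground truth (for synthetic data), the gaze
# trace and the configuration; the JSON sidecar written next to reports
# carries the config and seed for provenance.

#' Write a dataset to disk
#'
#' @param x A `reading_sim`, `meg_recording`, or any result list.
#' @param path Output file path (`.rds`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#' @param path File path.
#' @return The stored object.
#' @export
read_dataset <- function(path) readRDS(path)

#' Write a machine-readable JSON report
#'
#' @param report Named list (component counts, correlations, parcel
#'   tables, ...); data frames are serialized as column lists.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", force = TRUE)
  invisible(path)
}
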