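#' Event table: events x detectors matrix of cytometer values
#'
#' Thin container for the values recorded for one sample: a numeric matrix
#' with one row per event and one named column per detector, plus the pair of
#' columns designated as forward/side scatter. Values are kept on the stored
#' linear scale; no transform is applied at construction. Fluorescence values
#' may be negative (baseline-subtracted area parameters routinely are), but
#' non-finite values are rejected rather than dropped.
#'
#' @param values numeric matrix, events x detectors, with unique column names.
#' @param scatter_channels character vector of length 0 or 2 naming the
#'   forward and side scatter columns. Defaults to the columns matching
#'   "FSC-A" / "SSC-A" (case-insensitive) if present.
#' @return an object of class `event_table` with elements `values`,
#'   `detectors` and `scatter_channels`.
#' @export
event_table <- function(values, scatter_channels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    fs_stop("bad_events", "'values' must be a numeric matrix")
  if (nrow(values) < 1L)
    fs_stop("bad_events", "event table must contain at least one event")
  dn <- colnames(values)
  if (is.null(dn) || anyDuplicated(dn) || any(!nzchar(dn)))
    fs_stop("bad_events", "detector names must be present and unique")
  if (!all(is.finite(values)))
    fs_stop("nonfinite_values", "event data contain non-finite values")
  if (is.null(scatter_channels)) {
    scatter_channels <- dn[tolower(dn) %in% c("fsc-a", "ssc-a")]
    if (length(scatter_channels) != 2L) scatter_channels <- character(0)
  }
  if (!all(scatter_channels %in% dn))
    fs_stop("detector_not_found", sprintf(
      "scatter channel(s) %s not among detectors",
      paste(setdiff(scatter_channels, dn), collapse = ", ")))
  structure(
    list(values = values, detectors = dn, scatter_channels = scatter_channels),
    class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table: %d events x %d detectors>\n",
              nrow(x$values), length(x$detectors)))
  cat("  detectors:", paste(x$detectors, collapse = ", "), "\n")
  if (length(x$scatter_channels))
    cat("  scatter:", paste(x$scatter_channels, collapse = "/"), "\n")
  invisible(x)
}

#' @export
dim.event_table <- function(x) dim(x$values)

# fluorescence detector names (everything that is not scatter)
fluor_detectors <- function(et) setdiff(et$detectors, et$scatter_channels)

#' Extract the fluorescence submatrix of an event table
#'
#' @param et an [event_table()].
#' @param detectors optional character vector selecting/ordering columns;
#'   defaults to all non-scatter detectors in stored order.
#' @return numeric matrix events x detectors.
#' @export
fluor_values <- function(et, detectors = NULL) {
  if (is.null(detectors)) detectors <- fluor_detectors(et)
  missing <- setdiff(detectors, et$detectors)
  if (length(missing))
    fs_stop("detector_not_found",
            paste("detector(s) not found:", paste(missing, collapse = ", ")))
  et$values[, detectors, drop = FALSE]
}

# subset rows of an event table, keeping metadata
subset_events <- function(et, idx) {
  event_table(et$values[idx, , drop = FALSE], et$scatter_channels)
}
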