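#' Control set: gated or raw single-color controls, one per dye
#'
#' Holds one [event_table()] per dye, the dye -> primary-detector assignment
#' (possibly `NA` meaning "resolve automatically"), and an optional unstained
#' control. All controls share a harmonized detector set in the order of the
#' first control.
#'
#' @param controls named list of [event_table()], names are dye names.
#' @param primary named character vector (dye -> detector name), `NA` entries
#'   meaning automatic resolution by highest median signal.
#' @param unstained optional [event_table()] for the unstained control.
#' @return object of class `control_set`.
#' @export
control_set <- function(controls, primary = NULL, unstained = NULL) {
  dyes <- names(controls)
  if (is.null(dyes) || anyDuplicated(dyes) || any(!nzchar(dyes)))
    fs_stop("duplicate_dye", "dye names must be present and unique")
  if (!all(vapply(controls, inherits, TRUE, "event_table")))
    fs_stop("bad_events", "all controls must be event_table objects")
  ref <- controls[[1]]$detectors
  for (nm in dyes) {
    det <- controls[[nm]]$detectors
    if (!setequal(det, ref))
      fs_stop("detector_mismatch",
              sprintf("control '%s' has a different detector set", nm))
    if (!identical(det, ref)) {  # harmonize order to the first control
      controls[[nm]] <- event_table(controls[[nm]]$values[, ref, drop = FALSE],
                                    controls[[nm]]$scatter_channels)
    }
  }
  if (!is.null(unstained)) {
    if (!setequal(unstained$detectors, ref))
      fs_stop("detector_mismatch", "unstained control has a different detector set")
    unstained <- event_table(unstained$values[, ref, drop = FALSE],
                             unstained$scatter_channels)
  }
  if (is.null(primary)) primary <- stats::setNames(rep(NA_character_, length(dyes)), dyes)
  primary <- primary[dyes]
  names(primary) <- dyes
  fl <- fluor_detectors(controls[[1]])
  bad <- primary[!is.na(primary) & !(primary %in% fl)]
  if (length(bad))
    fs_stop("detector_not_found",
            paste("primary detector(s) not found:", paste(bad, collapse = ", ")))
  structure(list(controls = controls, primary = primary,
                 unstained = unstained, detectors = ref),
            class = "control_set")
}

#' @export
print.control_set <- function(x, ...) {
  cat(sprintf("<control_set: %d dyes, %d detectors%s>\n",
              length(x$controls), length(x$detectors),
              if (is.null(x$unstained)) "" else ", with unstained control"))
  invisible(x)
}

#' Read a control index CSV
#'
#' Expected columns: `file`, `dye`, `primary_detector` (detector name or
#' "AUTO"), `unstained` (0/1). At most one row may be flagged unstained.
#'
#' @param path path to the index CSV.
#' @return data.frame with normalized columns.
#' @export
read_control_index <- function(path) {
  if (!file.exists(path)) fs_stop("missing_file", paste("file not found:", path))
  idx <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("file", "dye")
  if (!all(need %in% names(idx)))
    fs_stop("bad_index", "control index needs at least columns 'file' and 'dye'")
  if (is.null(idx$primary_detector)) idx$primary_detector <- "AUTO"
  if (is.null(idx$unstained)) idx$unstained <- 0L
  idx$unstained <- as.integer(idx$unstained)
  if (sum(idx$unstained) > 1L)
    fs_stop("bad_index", "at most one control may be flagged as unstained")
  if (anyDuplicated(idx$dye[idx$unstained == 0L]))
    fs_stop("duplicate_dye", "duplicate dye names in control index")
  idx
}

#' Read a set of single-color control FCS files
#'
#' @param index data.frame as returned by [read_control_index()], or a path
#'   to the index CSV.
#' @param dir directory that `index$file` entries are relative to.
#' @return a raw (ungated) [control_set()].
#' @export
read_control_set <- function(index, dir = ".") {
  if (is.character(index)) index <- read_control_index(index)
  ctl <- list(); primary <- character(0); unst <- NULL
  for (r in seq_len(nrow(index))) {
    path <- file.path(dir, index$file[r])
    et <- read_fcs(path)
    if (index$unstained[r] == 1L) {
      unst <- et
    } else {
      dye <- index$dye[r]
      if (dye %in% names(ctl))
        fs_stop("duplicate_dye", paste("duplicate dye name:", dye))
      pd <- index$primary_detector[r]
      if (!is.na(pd) && toupper(pd) != "AUTO" && !(pd %in% et$detectors))
        fs_stop("detector_not_found",
                sprintf("primary detector '%s' absent from '%s'", pd, index$file[r]))
      ctl[[dye]] <- et
      primary[dye] <- if (is.na(pd) || toupper(pd) == "AUTO") NA_character_ else pd
    }
  }
  control_set(ctl, primary, unst)
}
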