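# CSV/TSV output of spillover matrices, spreading matrices and traces.

#' Write a spillover (or spreading) matrix as CSV
#'
#' Layout: header row `dye,<detector names>`, one row per dye, values at full
#' double precision so that re-reading reproduces the matrix bit-exactly.
#'
#' @param S numeric matrix with dye rownames and detector colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spillover_csv <- function(S, path) {
  if (is.null(rownames(S)) || is.null(colnames(S)))
    fs_stop("bad_matrix", "matrix must have dye rownames and detector colnames")
  vals <- apply(S, 2, function(col) sprintf("%.17g", col))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(S))
  lines <- c(paste(c("dye", colnames(S)), collapse = ","),
             vapply(seq_len(nrow(S)), function(i)
               paste(c(rownames(S)[i], vals[i, ]), collapse = ","), ""))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) fs_stop("unwritable_path", paste("cannot write to", path))
  invisible(path)
}

#' Read a spillover matrix written by [write_spillover_csv()]
#'
#' @param path CSV path.
#' @return numeric matrix with dye rownames and detector colnames.
#' @export
read_spillover_csv <- function(path) {
  if (!file.exists(path)) fs_stop("missing_file", paste("file not found:", path))
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write a convergence trace as TSV
#'
#' One line per refinement iteration with the iteration index, active scale,
#' standard deviation of compensation-error slopes, maximum absolute error,
#' moving average of the per-iteration decrease in that standard deviation,
#' and the damping factor applied.
#'
#' @param trace data.frame as returned in `$trace` by
#'   [refine_until_convergence()] (possibly 0-row).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  ok <- tryCatch({
    utils::write.table(trace, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) fs_stop("unwritable_path", paste("cannot write to", path))
  invisible(path)
}
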