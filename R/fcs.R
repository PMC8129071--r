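# Minimal FCS 3.0/3.1 reading and FCS 3.1 writing.
#
# Only the subset of the standard needed for single-color compensation
# controls is supported: list-mode ($MODE/L) data, $DATATYPE F (float32),
# D (float64) or I (16/32-bit integer), uniform $PnB per file, byte order
# 1,2,3,4 or 4,3,2,1. Detector names come from $PnN with $PnS as fallback.

read_fcs_text <- function(raw, beg, end) {
  txt <- rawToChar(raw[(beg + 1L):(end + 1L)])
  delim <- substr(txt, 1L, 1L)
  body <- substr(txt, 2L, nchar(txt))
  # trailing delimiter is required by the standard; tolerate its absence
  if (substr(body, nchar(body), nchar(body)) == delim)
    body <- substr(body, 1L, nchar(body) - 1L)
  fields <- strsplit(body, delim, fixed = TRUE)[[1]]
  if (length(fields) %% 2L == 1L) fields <- c(fields, "")
  keys <- toupper(trimws(fields[seq(1L, length(fields), by = 2L)]))
  vals <- trimws(fields[seq(2L, length(fields), by = 2L)])
  names(vals) <- keys
  vals
}

#' Read an FCS 3.0/3.1 file
#'
#' Minimal list-mode reader returning the event matrix and detector names.
#' `$PnN` is used as the detector name, with `$PnS` as fallback when `$PnN`
#' is empty.
#'
#' @param path path to an FCS file.
#' @param scatter_channels passed to [event_table()]; by default channels
#'   named like FSC-A/SSC-A are designated as scatter.
#' @return an [event_table()].
#' @export
read_fcs <- function(path, scatter_channels = NULL) {
  if (!file.exists(path))
    fs_stop("missing_file", paste("file not found:", path))
  raw <- readBin(path, "raw", n = file.info(path)$size)
  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1"))
    fs_stop("bad_fcs", paste0("unsupported FCS version '", version, "' in ", path))
  off <- function(i, j) as.numeric(trimws(rawToChar(raw[i:j])))
  text_beg <- off(11, 18); text_end <- off(19, 26)
  data_beg <- off(27, 34); data_end <- off(35, 42)
  kw <- read_fcs_text(raw, text_beg, text_end)
  if (is.na(data_beg) || data_beg == 0) data_beg <- as.numeric(kw[["$BEGINDATA"]])
  if (is.na(data_end) || data_end == 0) data_end <- as.numeric(kw[["$ENDDATA"]])
  npar <- as.integer(kw[["$PAR"]])
  ntot <- as.integer(kw[["$TOT"]])
  dtype <- toupper(kw[["$DATATYPE"]])
  byteord <- kw[["$BYTEORD"]]
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  bits <- as.integer(kw[[paste0("$P", 1L, "B")]])
  pnb <- vapply(seq_len(npar), function(i) as.integer(kw[[paste0("$P", i, "B")]]), 1L)
  if (length(unique(pnb)) != 1L)
    fs_stop("bad_fcs", "mixed $PnB widths are not supported")
  nval <- npar * ntot
  con <- raw[(data_beg + 1L):(data_end + 1L)]
  data <- switch(dtype,
    F = readBin(con, "double", n = nval, size = 4L, endian = endian),
    D = readBin(con, "double", n = nval, size = 8L, endian = endian),
    I = {
      if (bits == 16L)
        readBin(con, "integer", n = nval, size = 2L, signed = FALSE, endian = endian)
      else
        readBin(con, "integer", n = nval, size = 4L, endian = endian)
    },
    fs_stop("bad_fcs", paste("unsupported $DATATYPE", dtype)))
  mat <- matrix(data, nrow = ntot, ncol = npar, byrow = TRUE)
  nm <- vapply(seq_len(npar), function(i) {
    n <- kw[[paste0("$P", i, "N")]]
    if (is.null(n) || !nzchar(n)) n <- kw[[paste0("$P", i, "S")]]
    if (is.null(n) || !nzchar(n)) n <- paste0("P", i)
    n
  }, "")
  colnames(mat) <- nm
  event_table(mat, scatter_channels)
}

#' Write an event table as a minimal FCS 3.1 file
#'
#' Intended for synthetic fixtures: list mode, float32 data, little-endian.
#' Files written by this function round-trip through [read_fcs()] to float
#' precision.
#'
#' @param et an [event_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(et, path) {
  if (!inherits(et, "event_table"))
    fs_stop("bad_events", "'et' must be an event_table")
  mat <- et$values
  npar <- ncol(mat); ntot <- nrow(mat)
  d <- "/"
  kv <- c(
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0", "$PAR" = as.character(npar), "$TOT" = as.character(ntot))
  for (i in seq_len(npar)) {
    kv[paste0("$P", i, "N")] <- colnames(mat)[i]
    kv[paste0("$P", i, "B")] <- "32"
    kv[paste0("$P", i, "E")] <- "0,0"
    kv[paste0("$P", i, "R")] <- "262144"
  }
  data_len <- 4L * npar * ntot
  build_text <- function(beg_data, end_data) {
    kv2 <- c(kv, "$BEGINDATA" = sprintf("%d", beg_data),
             "$ENDDATA" = sprintf("%d", end_data))
    paste0(d, paste0(names(kv2), d, unname(kv2), d, collapse = ""))
  }
  header_len <- 58L
  # iterate: text length depends on the offsets printed inside it
  text_beg <- header_len
  text <- build_text(0L, 0L)
  for (k in 1:3) {
    data_beg <- text_beg + nchar(text)
    data_end <- data_beg + data_len - 1L
    text2 <- build_text(data_beg, data_end)
    if (nchar(text2) == nchar(text)) { text <- text2; break }
    text <- text2
  }
  data_beg <- text_beg + nchar(text)
  data_end <- data_beg + data_len - 1L
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_beg, text_beg + nchar(text) - 1L,
                    data_beg, data_end, 0L, 0L)
  stopifnot(nchar(header) == header_len)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(mat)), con, size = 4L, endian = "little")
  invisible(path)
}
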