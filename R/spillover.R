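# Spillover estimation and iterative refinement.
#
# The observed event vector y (length c, channels) relates to the true dye
# vector x (length d) through the row-normalized d x c spillover matrix S:
# x S = y on average. Compensating with an erroneous estimate U = S + T
# leaves residual slopes E[i, j] (dye j vs dye i in the compensated control
# for dye i), and for the average event the estimation error satisfies
# T = -E U exactly. The refinement loop measures E by robust regression,
# applies S <- rownorm(S + E S), and repeats until max|E| is negligible.

#' Refinement configuration
#'
#' Thresholds driving [refine_until_convergence()]. Defaults: switch from
#' linear to bi-exponential regression scale when the maximum absolute
#' compensation error drops below 1e-2; stop at 1e-4; detect oscillations
#' when the moving average (window 10, initial value 1) of the per-iteration
#' decrease in sd(E) falls below 1e-6, after which only a 10% fraction of
#' each update is applied.
#'
#' @param scale_switch_threshold max|E| below which regression switches to
#'   bi-exponential scale.
#' @param convergence_threshold max|E| declaring convergence.
#' @param oscillation_threshold moving-average-of-decrease level that
#'   triggers damping.
#' @param oscillation_window moving-average window (iterations).
#' @param oscillation_init initial value padded into the moving average so
#'   damping cannot trigger spuriously in early iterations.
#' @param damping_fraction fraction of the update applied once damping is on
#'   (it stays on for all remaining iterations).
#' @param max_iterations iteration cap; exceeding it returns the last
#'   iterate with status "max_iterations" rather than raising.
#' @param huber_k Huber tuning constant for all robust regressions.
#' @return list of class `spillover_config`.
#' @export
spillover_config <- function(scale_switch_threshold = 1e-2,
                             convergence_threshold = 1e-4,
                             oscillation_threshold = 1e-6,
                             oscillation_window = 10L,
                             oscillation_init = 1,
                             damping_fraction = 0.10,
                             max_iterations = 100L,
                             huber_k = 1.345) {
  stopifnot(scale_switch_threshold > 0, convergence_threshold > 0,
            oscillation_threshold > 0, oscillation_window >= 1,
            damping_fraction > 0, damping_fraction <= 1, max_iterations >= 1)
  structure(list(scale_switch_threshold = scale_switch_threshold,
                 convergence_threshold = convergence_threshold,
                 oscillation_threshold = oscillation_threshold,
                 oscillation_window = as.integer(oscillation_window),
                 oscillation_init = oscillation_init,
                 damping_fraction = damping_fraction,
                 max_iterations = as.integer(max_iterations),
                 huber_k = huber_k),
            class = "spillover_config")
}

#' Resolve the primary detector of a control
#'
#' The primary channel h of a dye is the detector carrying its highest
#' signal. An explicit assignment is honored; otherwise the non-scatter
#' detector with the highest median fluorescence is chosen (ties resolved by
#' detector order).
#'
#' @param et gated [event_table()] for the control.
#' @param assigned detector name or `NA`/"AUTO" for automatic resolution.
#' @return detector name.
#' @export
resolve_primary <- function(et, assigned = NA_character_) {
  if (!is.na(assigned) && toupper(assigned) != "AUTO") {
    if (!(assigned %in% fluor_detectors(et)))
      fs_stop("detector_not_found",
              paste("assigned primary detector not found:", assigned))
    return(assigned)
  }
  fl <- fluor_detectors(et)
  med <- apply(fluor_values(et, fl), 2, stats::median)
  fl[which.max(med)]
}

# construct a spillover matrix object: rows dyes, columns fluorescence
# detectors, attribute "primary" = column index of each dye's primary
new_spillover <- function(coef, primary_cols) {
  if (nrow(coef) > ncol(coef))
    fs_stop("bad_matrix", "more dyes than detectors (d must be <= c)")
  attr(coef, "primary") <- primary_cols
  class(coef) <- c("spillover_matrix", class(coef))
  coef
}

#' @export
print.spillover_matrix <- function(x, ...) {
  cat(sprintf("<spillover_matrix: %d dyes x %d detectors>\n", nrow(x), ncol(x)))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Initial spillover matrix from robust regressions
#'
#' For each control i the coefficient into channel j is the Huber-robust
#' slope of the j-th detector signal on the primary-detector signal over the
#' gated events; the primary coefficient is 1 by row normalization.
#'
#' @param Y named list (by dye) of gated fluorescence matrices
#'   (events x detectors, shared column order).
#' @param primary named character vector: dye -> primary detector name.
#' @param k Huber tuning constant.
#' @return a `spillover_matrix` (d x c, rows dyes, columns detectors).
#' @export
initial_spillover <- function(Y, primary, k = 1.345) {
  dyes <- names(Y)
  dets <- colnames(Y[[1]])
  S <- matrix(0, length(dyes), length(dets), dimnames = list(dyes, dets))
  pcols <- stats::setNames(match(primary[dyes], dets), dyes)
  if (anyNA(pcols)) fs_stop("detector_not_found", "unknown primary detector")
  for (i in seq_along(dyes)) {
    h <- pcols[i]
    x <- Y[[i]][, h]
    S[i, h] <- 1
    for (j in seq_along(dets)[-h])
      S[i, j] <- fit_slope_robust(x, Y[[i]][, j], k, warn = FALSE)$slope
  }
  new_spillover(S, pcols)
}

#' Compensate observed events with a spillover matrix
#'
#' Solves x S = y per event: matrix inversion when the matrix is square
#' (classical cytometers), least squares via QR when detectors outnumber
#' dyes (spectral unmixing).
#'
#' @param y events x detectors matrix (or an [event_table()], from which the
#'   matching fluorescence columns are taken).
#' @param spill spillover matrix (d x c, detector colnames).
#' @return events x dyes matrix of compensated (dye-space) values.
#' @export
compensate <- function(y, spill) {
  Y <- if (inherits(y, "event_table")) fluor_values(y, colnames(spill)) else y
  if (!identical(colnames(Y), colnames(spill)))
    fs_stop("detector_mismatch", "event columns do not match spillover columns")
  d <- nrow(spill); c_ <- ncol(spill)
  Sm <- unclass(spill); attr(Sm, "primary") <- NULL
  if (d == c_) {
    Sinv <- tryCatch(solve(Sm), error = function(e)
      fs_stop("singular_matrix", "spillover matrix is singular"))
    X <- Y %*% Sinv
  } else {
    qr_ts <- qr(t(Sm))
    if (qr_ts$rank < d)
      fs_stop("singular_matrix", "spillover matrix is rank-deficient")
    X <- t(qr.coef(qr_ts, t(Y)))
  }
  colnames(X) <- rownames(spill)
  X
}

#' Residual compensation-error matrix
#'
#' E[i, j] is the robust slope of dye j versus dye i over the compensated
#' events of the control for dye i; the diagonal is zero by definition. When
#' a bi-exponential transform is active, the regression runs on transformed
#' values and the slope is mapped back to linear scale through the two
#' points of the fitted line at the extreme primary values (chord slope of
#' the back-transformed endpoints).
#'
#' @param X named list (by dye) of compensated matrices (events x dyes).
#' @param transform `NULL` for linear scale, or a [fit_biexp()] object.
#' @param k Huber tuning constant.
#' @return d x d matrix with zero diagonal.
#' @export
compensation_errors <- function(X, transform = NULL, k = 1.345) {
  dyes <- names(X)
  d <- length(dyes)
  E <- matrix(0, d, d, dimnames = list(dyes, dyes))
  for (i in seq_len(d)) {
    xi <- X[[i]][, i]
    for (j in seq_len(d)[-i])
      E[i, j] <- error_slope(xi, X[[i]][, j],
                             if (is.null(transform)) NULL else transform[[dyes[i]]],
                             if (is.null(transform)) NULL else transform[[dyes[j]]],
                             k)
  }
  E
}

# one residual compensation slope, in linear scale or (when widths are
# given) measured in bi-exponential scale and mapped back to linear through
# the chord of the fitted line at the extreme primary values
error_slope <- function(x, y, width_x = NULL, width_y = NULL, k = 1.345) {
  if (is.null(width_x))
    return(fit_slope_robust(x, y, k, warn = FALSE)$slope)
  tx <- biexp_apply(x, width_x)
  f <- fit_slope_robust(tx, biexp_apply(y, width_y), k, warn = FALSE)
  t1 <- min(tx); t2 <- max(tx)
  y1 <- biexp_invert(f$intercept + f$slope * t1, width_y)
  y2 <- biexp_invert(f$intercept + f$slope * t2, width_y)
  (y2 - y1) / (biexp_invert(t2, width_x) - biexp_invert(t1, width_x))
}

#' One refinement step
#'
#' Applies the error-propagation update: the non-normalized matrix is
#' S + alpha * (E S); each row is then renormalized by its primary entry so
#' the primary coefficient stays exactly 1.
#'
#' @param S current `spillover_matrix`.
#' @param E compensation-error matrix (d x d).
#' @param alpha update fraction (1 normally, the damping fraction once
#'   oscillations are detected).
#' @return updated `spillover_matrix`.
#' @export
refine_step <- function(S, E, alpha = 1) {
  pcols <- attr(S, "primary")
  Sm <- unclass(S); attr(Sm, "primary") <- NULL
  Shat <- Sm + alpha * (E %*% Sm)
  pe <- Shat[cbind(seq_len(nrow(Shat)), pcols)]
  if (any(pe == 0))
    fs_stop("singular_matrix", "zero primary entry after update")
  out <- Shat / pe
  new_spillover(out, pcols)
}

offdiag <- function(E) E[row(E) != col(E)]

#' Iteratively refine a spillover matrix to convergence
#'
#' Loop: compensate every control, measure the residual error matrix E,
#' record the trace, stop when max|E| falls below the convergence threshold;
#' otherwise switch to bi-exponential regression scale once max|E| < the
#' switch threshold (transform widths frozen at the switch), update the
#' oscillation detector (moving average of the decrease in sd(E)), engage
#' 10% damping permanently once it fires, and apply one refinement step.
#'
#' @param Y named list (by dye) of gated fluorescence matrices.
#' @param S0 initial `spillover_matrix` (from [initial_spillover()]).
#' @param config a [spillover_config()].
#' @return list with `spillover` (final matrix), `trace` (data.frame:
#'   iteration, scale, sd_error, max_error, ma_decrease, damping),
#'   `compensated` (list of final compensated controls), `errors` (final E),
#'   `status` ("converged" or "max_iterations") and `iterations`.
#' @export
refine_until_convergence <- function(Y, S0, config = spillover_config()) {
  S <- S0
  transform <- NULL
  damped <- FALSE
  decreases <- numeric(0)
  prev_sd <- NULL
  trace <- list()
  status <- "max_iterations"
  X <- NULL; E <- NULL
  for (t in 0:config$max_iterations) {
    X <- lapply(Y, compensate, spill = S)
    E <- compensation_errors(X, transform, config$huber_k)
    sd_e <- stats::sd(offdiag(E))
    max_e <- max(abs(E))
    if (!is.null(prev_sd)) decreases <- c(decreases, prev_sd - sd_e)
    prev_sd <- sd_e
    padded <- c(rep(config$oscillation_init, config$oscillation_window), decreases)
    ma <- mean(utils::tail(padded, config$oscillation_window))
    if (!damped && ma < config$oscillation_threshold) damped <- TRUE
    alpha <- if (damped) config$damping_fraction else 1
    trace[[length(trace) + 1L]] <- data.frame(
      iteration = t, scale = if (is.null(transform)) "linear" else "biexp",
      sd_error = sd_e, max_error = max_e, ma_decrease = ma, damping = alpha)
    if (max_e < config$convergence_threshold) { status <- "converged"; break }
    if (t == config$max_iterations) break
    if (is.null(transform) && max_e < config$scale_switch_threshold)
      transform <- fit_biexp(X)
    S <- refine_step(S, E, alpha)
  }
  list(spillover = S, trace = do.call(rbind, trace), compensated = X,
       errors = E, status = status, iterations = length(trace),
       transform = transform)
}

#' Traditional positive/negative-population spillover (comparison oracle)
#'
#' The classical calculation: split each control's events into positive and
#' negative populations on the primary channel (1-D 2-means initialized at
#' the observed extremes, hence deterministic) and take, for each secondary
#' channel, the ratio of the median differences. Controls whose populations
#' are not separable yield flagged (NA) coefficients.
#'
#' @param Y named list (by dye) of gated fluorescence matrices.
#' @param primary named character vector: dye -> primary detector name.
#' @param min_separation minimum relative separation of the primary-channel
#'   medians, below which the control is flagged.
#' @return a `spillover_matrix` possibly containing NA rows; flagged dyes
#'   are listed in attribute `flagged`.
#' @export
traditional_spillover <- function(Y, primary, min_separation = 1e-8) {
  dyes <- names(Y)
  dets <- colnames(Y[[1]])
  S <- matrix(NA_real_, length(dyes), length(dets), dimnames = list(dyes, dets))
  pcols <- stats::setNames(match(primary[dyes], dets), dyes)
  flagged <- character(0)
  for (i in seq_along(dyes)) {
    h <- pcols[i]
    v <- Y[[i]][, h]
    if (min(v) == max(v)) { flagged <- c(flagged, dyes[i]); next }
    km <- stats::kmeans(v, centers = matrix(c(min(v), max(v)), 2, 1))
    pos <- km$cluster == which.max(km$centers)
    mp <- stats::median(v[pos]); mn <- stats::median(v[!pos])
    if (!is.finite(mp - mn) ||
        abs(mp - mn) <= min_separation * max(abs(mp), abs(mn), 1)) {
      flagged <- c(flagged, dyes[i])
      next
    }
    S[i, ] <- (apply(Y[[i]][pos, , drop = FALSE], 2, stats::median) -
               apply(Y[[i]][!pos, , drop = FALSE], 2, stats::median)) / (mp - mn)
    S[i, h] <- 1
  }
  out <- new_spillover(S, pcols)
  attr(out, "flagged") <- flagged
  out
}
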