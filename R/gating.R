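# Automated scatter gating: trim -> density maxima -> tessellation ->
# region -> second tessellation -> density-threshold convex hull.
#
# The goal is to isolate the cell (or bead) population on FSC/SSC and drop
# debris near the origin, with no per-sample tuning. Two successive
# tessellations around density maxima first pick the target peak among all
# peaks, then separate it from close-by peaks inside a median +/- 3*MAD
# region; the gate itself is the convex hull of the points of the winning
# tile whose local density exceeds 33% of the within-tile density range.

#' Trim scatter extremes
#'
#' Removes events outside the central empirical quantile interval of FSC or
#' SSC (default 1%-99% on each axis).
#'
#' @param et an [event_table()] with scatter channels.
#' @param quantiles lower/upper quantile pair.
#' @return list with `events` (trimmed [event_table()]), `keep` (logical
#'   index into the input) and `ranges` (2x2 matrix of trimmed axis ranges,
#'   rows FSC/SSC).
#' @export
trim_extremes <- function(et, quantiles = c(0.01, 0.99)) {
  if (length(et$scatter_channels) != 2L)
    fs_stop("no_scatter", "event table has no designated scatter channels")
  if (nrow(et$values) < 100L)
    fs_stop("too_few_events", "need at least 100 events to gate")
  sc <- et$values[, et$scatter_channels, drop = FALSE]
  keep <- rep(TRUE, nrow(sc))
  for (j in 1:2) {
    q <- stats::quantile(sc[, j], quantiles, names = FALSE, type = 7)
    keep <- keep & sc[, j] >= q[1] & sc[, j] <= q[2]
  }
  out <- subset_events(et, keep)
  ranges <- apply(out$values[, et$scatter_channels, drop = FALSE], 2, range)
  list(events = out, keep = keep, ranges = t(ranges))
}

#' Estimate a 2-D scatter density surface
#'
#' Gaussian-kernel density on a regular grid via [MASS::kde2d()], with
#' per-axis bandwidth equal to the normal reference rule
#' ([MASS::bandwidth.nrd()]) times `bandwidth_factor`.
#'
#' @param xy two-column matrix of points (FSC, SSC).
#' @param bandwidth_factor positive multiplier of the reference bandwidth.
#' @param gridsize grid resolution per axis.
#' @param lims optional `c(xmin, xmax, ymin, ymax)` limits.
#' @return list with `x`, `y` (grid axes), `z` (density matrix, x by y) and
#'   `bandwidth`.
#' @export
estimate_density <- function(xy, bandwidth_factor = 3, gridsize = 100L,
                             lims = NULL) {
  if (nrow(unique(xy)) < 3L)
    fs_stop("too_few_events", "need at least 3 distinct points for a density")
  h <- c(MASS::bandwidth.nrd(xy[, 1]), MASS::bandwidth.nrd(xy[, 2]))
  if (any(h <= 0)) {
    # reference rule collapses when IQR and sd interact badly; fall back to sd
    h <- 4 * c(stats::sd(xy[, 1]), stats::sd(xy[, 2])) * nrow(xy)^(-1/6)
  }
  if (any(h <= 0))
    fs_stop("zero_variance", "zero variance on a scatter axis")
  h <- h * bandwidth_factor
  if (is.null(lims)) lims <- c(range(xy[, 1]), range(xy[, 2]))
  kd <- MASS::kde2d(xy[, 1], xy[, 2], h = h, n = gridsize, lims = lims)
  list(x = kd$x, y = kd$y, z = kd$z, bandwidth = h)
}

# box-filter a grid with shrunken windows at the boundary (no padding);
# `radius` = number of cells included on each side of the center
smooth_grid <- function(z, radius) {
  if (radius <= 0) return(z)
  n <- nrow(z); m <- ncol(z)
  sat <- matrix(0, n + 1L, m + 1L)  # summed-area table
  sat[-1L, -1L] <- t(apply(apply(z, 2L, cumsum), 1L, cumsum))
  i1 <- pmax(seq_len(n) - radius, 1L); i2 <- pmin(seq_len(n) + radius, n)
  j1 <- pmax(seq_len(m) - radius, 1L); j2 <- pmin(seq_len(m) + radius, m)
  out <- matrix(0, n, m)
  for (j in seq_len(m)) {
    a <- sat[cbind(i2 + 1L, j2[j] + 1L)] - sat[cbind(i1, j2[j] + 1L)] -
         sat[cbind(i2 + 1L, j1[j])] + sat[cbind(i1, j1[j])]
    out[, j] <- a / ((i2 - i1 + 1L) * (j2[j] - j1[j] + 1L))
  }
  out
}

#' Locate density maxima on a surface
#'
#' The density grid is smoothed by a moving average (box filter of the given
#' window radius, windows shrunk at the boundary); local maxima are grid
#' cells strictly greater than all 8 neighbors. Maxima are ordered by
#' decreasing smoothed density, ties broken by lower FSC then lower SSC. A
#' flat surface has no strict maxima; the global maximum (same tie-break) is
#' returned as fallback so at least one maximum always exists.
#'
#' @param surface as returned by [estimate_density()].
#' @param window moving-average radius in grid cells.
#' @return data.frame with columns `x`, `y`, `density`, ordered by
#'   decreasing density.
#' @export
find_maxima <- function(surface, window = 3L) {
  zs <- smooth_grid(surface$z, window)
  n <- nrow(zs); m <- ncol(zs)
  pad <- matrix(-Inf, n + 2L, m + 2L)
  pad[2:(n + 1L), 2:(m + 1L)] <- zs
  is_max <- matrix(TRUE, n, m)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    nb <- pad[(2:(n + 1L)) + di, (2:(m + 1L)) + dj]
    is_max <- is_max & (zs > nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {  # flat / plateau fallback: global maximum
    idx <- which(zs == max(zs), arr.ind = TRUE)
    ordg <- order(surface$x[idx[, 1]], surface$y[idx[, 2]])
    idx <- idx[ordg[1L], , drop = FALSE]
  }
  out <- data.frame(x = surface$x[idx[, 1]], y = surface$y[idx[, 2]],
                    density = zs[idx])
  out[order(-out$density, out$x, out$y), , drop = FALSE]
}

#' Assign points to the nearest density maximum (Voronoi tessellation)
#'
#' Euclidean nearest-maximum assignment in axis-normalized coordinates (each
#' axis scaled by its trimmed range so FSC and SSC are commensurate). A point
#' equidistant from several maxima goes to the maximum with higher density
#' (maxima are ordered by decreasing density).
#'
#' @param xy two-column matrix of points.
#' @param maxima data.frame from [find_maxima()].
#' @param ranges 2x2 matrix of axis ranges (rows = axes) used for
#'   normalization; defaults to the range of `xy`.
#' @return integer vector: row index into `maxima` for each point.
#' @export
tessellate <- function(xy, maxima, ranges = NULL) {
  if (nrow(maxima) < 1L) fs_stop("no_maxima", "need at least one maximum")
  if (is.null(ranges)) ranges <- rbind(range(xy[, 1]), range(xy[, 2]))
  sx <- max(ranges[1, 2] - ranges[1, 1], .Machine$double.eps)
  sy <- max(ranges[2, 2] - ranges[2, 1], .Machine$double.eps)
  px <- xy[, 1] / sx; py <- xy[, 2] / sy
  mx <- maxima$x / sx; my <- maxima$y / sy
  d2 <- outer(px, mx, "-")^2 + outer(py, my, "-")^2
  max.col(-d2, ties.method = "first")
}

#' Select the target density maximum, ignoring the debris peak
#'
#' Maxima whose FSC *and* SSC coordinates both lie within the lowest 5% of
#' the respective trimmed range are treated as debris and discarded; the
#' densest survivor is the target. If every maximum is discarded the overall
#' densest one is returned as fallback.
#'
#' @param maxima data.frame from [find_maxima()].
#' @param ranges 2x2 matrix of trimmed axis ranges (rows FSC, SSC).
#' @param debris_fraction fraction of the range defining "low" (default 0.05).
#' @return single-row data.frame (the chosen maximum) with attribute
#'   `index` = its row position in `maxima`.
#' @export
select_target <- function(maxima, ranges, debris_fraction = 0.05) {
  tx <- ranges[1, 1] + debris_fraction * (ranges[1, 2] - ranges[1, 1])
  ty <- ranges[2, 1] + debris_fraction * (ranges[2, 2] - ranges[2, 1])
  low <- maxima$x < tx & maxima$y < ty
  pick <- if (all(low)) 1L else which(!low)[1L]  # maxima ordered by density
  out <- maxima[pick, , drop = FALSE]
  attr(out, "index") <- pick
  out
}

#' Rectangular region around the target tile
#'
#' Per axis: median +/- 3 x the mean absolute deviation about the median of
#' the tile's events, clipped to the observed data range.
#'
#' @param xy two-column matrix of the events in the selected tile.
#' @param mad_factor multiplier of the mean absolute deviation (default 3).
#' @return 2x2 matrix (rows = axes, columns = lower/upper bound).
#' @export
bound_region <- function(xy, mad_factor = 3) {
  if (nrow(xy) == 0L) fs_stop("empty_tile", "selected tile contains no events")
  out <- matrix(0, 2, 2)
  for (j in 1:2) {
    med <- stats::median(xy[, j])
    mad_mean <- mean(abs(xy[, j] - med))
    if (mad_mean == 0)
      fs_stop("degenerate_region", "zero spread in selected tile")
    out[j, ] <- pmin(pmax(c(med - mad_factor * mad_mean,
                            med + mad_factor * mad_mean),
                          min(xy[, j])), max(xy[, j]))
  }
  out
}

# bilinear interpolation of a density surface at arbitrary points
interp_density <- function(surface, px, py) {
  gx <- surface$x; gy <- surface$y; z <- surface$z
  ix <- findInterval(px, gx, all.inside = TRUE)
  iy <- findInterval(py, gy, all.inside = TRUE)
  fx <- (px - gx[ix]) / (gx[ix + 1L] - gx[ix])
  fy <- (py - gy[iy]) / (gy[iy + 1L] - gy[iy])
  fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1)
  z[cbind(ix, iy)] * (1 - fx) * (1 - fy) +
    z[cbind(ix + 1L, iy)] * fx * (1 - fy) +
    z[cbind(ix, iy + 1L)] * (1 - fx) * fy +
    z[cbind(ix + 1L, iy + 1L)] * fx * fy
}

# point-in-convex-polygon test (vertices oriented counter-clockwise)
in_convex_polygon <- function(px, py, vx, vy) {
  k <- length(vx)
  eps <- 1e-9 * (diff(range(vx)) * diff(range(vy)) + 1)
  inside <- rep(TRUE, length(px))
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    cr <- (vx[j] - vx[i]) * (py - vy[i]) - (vy[j] - vy[i]) * (px - vx[i])
    inside <- inside & (cr >= -eps)
  }
  inside
}

#' Compute the automatic scatter gate
#'
#' Full gating pipeline: trim extremes (1%/99%); density estimate (bandwidth
#' factor 3), moving-average maxima (window 3), tessellation, target
#' selection with the 5%-of-range debris rule; median +/- 3*MAD region;
#' finer density (factor 2), maxima (window 2), second tessellation; final
#' density (factor 1) on the winning tile; the gate is the convex hull of
#' the tile's points with density above 33% of the within-tile density
#' range. Gated events are the input events inside the hull.
#'
#' @param et an [event_table()] with scatter channels.
#' @param trim_quantiles trim quantile pair.
#' @param bandwidth_factors density bandwidth multipliers for the three
#'   estimation passes.
#' @param windows moving-average radii for the two maxima searches.
#' @param debris_fraction low-scatter fraction for the debris rule.
#' @param density_threshold fraction of the within-tile density range.
#' @param min_gated minimum number of events inside the hull.
#' @return list of class `flow_gate` with `polygon` (data.frame of hull
#'   vertices), `events` (gated [event_table()]), `inside` (logical over the
#'   input events) and `diagnostics`.
#' @export
compute_gate <- function(et, trim_quantiles = c(0.01, 0.99),
                         bandwidth_factors = c(3, 2, 1), windows = c(3L, 2L),
                         debris_fraction = 0.05, density_threshold = 0.33,
                         min_gated = 50L) {
  tr <- trim_extremes(et, trim_quantiles)
  xy <- tr$events$values[, tr$events$scatter_channels, drop = FALSE]
  ranges <- tr$ranges

  dens1 <- estimate_density(xy, bandwidth_factors[1])
  max1 <- find_maxima(dens1, windows[1])
  tile1 <- tessellate(xy, max1, ranges)
  target <- select_target(max1, ranges, debris_fraction)
  in_target <- tile1 == attr(target, "index")

  region <- bound_region(xy[in_target, , drop = FALSE])
  in_region <- xy[, 1] >= region[1, 1] & xy[, 1] <= region[1, 2] &
               xy[, 2] >= region[2, 1] & xy[, 2] <= region[2, 2]
  xy2 <- xy[in_region, , drop = FALSE]

  dens2 <- estimate_density(xy2, bandwidth_factors[2])
  max2 <- find_maxima(dens2, windows[2])
  tile2 <- tessellate(xy2, max2, region)
  in_tile2 <- tile2 == 1L  # tile of the highest (first) maximum
  xy3 <- xy2[in_tile2, , drop = FALSE]

  dens3 <- estimate_density(xy3, bandwidth_factors[3])
  dvals <- interp_density(dens3, xy3[, 1], xy3[, 2])
  thr <- min(dvals) + density_threshold * (max(dvals) - min(dvals))
  kept <- dvals > thr
  if (sum(kept) < 3L) kept <- dvals >= thr  # degenerate: flat density
  pts <- xy3[kept, , drop = FALSE]
  hull_idx <- grDevices::chull(pts[, 1], pts[, 2])  # counter-clockwise order
  hx <- pts[hull_idx, 1]; hy <- pts[hull_idx, 2]
  # ensure counter-clockwise orientation for the inclusion test
  area2 <- sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)
  if (area2 < 0) { hx <- rev(hx); hy <- rev(hy) }

  sc_all <- et$values[, et$scatter_channels, drop = FALSE]
  inside <- in_convex_polygon(sc_all[, 1], sc_all[, 2], hx, hy)
  if (sum(inside) < min_gated)
    fs_stop("gate_too_small",
            sprintf("only %d events inside the gate", sum(inside)))
  structure(list(
    polygon = data.frame(stats::setNames(list(hx, hy), et$scatter_channels)),
    events = subset_events(et, inside),
    inside = inside,
    diagnostics = list(maxima_first = max1, target = target, region = region,
                       maxima_second = max2, density_threshold = thr,
                       trimmed_ranges = ranges)),
    class = "flow_gate")
}

#' @export
print.flow_gate <- function(x, ...) {
  cat(sprintf("<flow_gate: %d/%d events inside a %d-vertex hull>\n",
              sum(x$inside), length(x$inside), nrow(x$polygon)))
  invisible(x)
}
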