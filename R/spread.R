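# Spillover spreading matrix (SSM) by quantile partitioning and two
# regressions.
#
# Compensation zeroes the mean of every secondary channel but spreads its
# variance: photon-counting noise makes the variance of any channel grow
# linearly with fluorescence, so after compensation the robust SD of a
# secondary dye C grows like sqrt of the primary fluorescence F,
# sigma^2 = SS^2 F + sigma0^2, with sigma0 the machine noise floor at zero
# fluorescence. Rather than requiring positive/negative populations, the
# events of each control are partitioned into quantile bins of the primary
# signal; a first regression (with intercept) of sigma on f_sqrt(F)
# estimates sigma0, and a second no-intercept regression of
# f_sqrt(sigma^2 - sigma0^2) on f_sqrt(F) gives the spreading coefficient.
# Skipping the sigma0 adjustment biases coefficients downward.

#' Signed square-root-like transform
#'
#' `f_sqrt(x) = sign(x) * (sqrt(|x| + 1) - 1)`: behaves like a square root
#' for large |x| but is smooth and linear through zero, so fluorescence
#' values that are negative or near zero can be transformed safely.
#'
#' @param x numeric vector.
#' @return transformed vector.
#' @export
f_sqrt <- function(x) sign(x) * (sqrt(abs(x) + 1) - 1)

#' Partition a control into quantile bins of primary fluorescence
#'
#' The bin count is the largest value in `ladder` leaving at least
#' `min_per_bin` events per bin. Within each bin the primary statistic is
#' the median fluorescence F and, for each secondary column, the robust SD
#' (84th percentile minus median, one Gaussian SD for normal data).
#'
#' @param primary numeric vector of compensated primary-dye values.
#' @param secondary numeric matrix (events x secondary dyes) or vector.
#' @param min_per_bin minimum events per bin.
#' @param ladder candidate bin counts, decreasing.
#' @return list with `F` (per-bin medians), `sigma` (bins x secondaries
#'   matrix of robust SDs), `count` (events per bin), `bins`.
#' @export
partition_quantiles <- function(primary, secondary, min_per_bin = 32L,
                                ladder = c(256L, 128L, 64L, 32L, 16L, 8L)) {
  n <- length(primary)
  if (is.vector(secondary)) secondary <- matrix(secondary, ncol = 1)
  stopifnot(nrow(secondary) == n)
  fits <- ladder[n %/% ladder >= min_per_bin]
  if (length(fits) == 0L)
    fs_stop("too_few_events",
            sprintf("need at least %d events for %d bins", min_per_bin * min(ladder),
                    min(ladder)))
  nbins <- fits[1L]
  ord <- order(primary)
  bin <- ceiling(seq_len(n) * nbins / n)  # near-equal counts, by rank
  ps <- primary[ord]
  Fm <- vapply(split(ps, bin), stats::median, 1.0)
  counts <- as.integer(table(bin))
  sig <- matrix(0, nbins, ncol(secondary),
                dimnames = list(NULL, colnames(secondary)))
  for (cidx in seq_len(ncol(secondary))) {
    v <- split(secondary[ord, cidx], bin)
    sig[, cidx] <- vapply(v, function(z)
      stats::quantile(z, 0.84, names = FALSE) - stats::median(z), 1.0)
  }
  list(F = unname(Fm), sigma = sig, count = counts, bins = nbins)
}

#' Estimate the zero-fluorescence noise floor sigma0
#'
#' Ordinary least squares of the per-bin robust SD on `f_sqrt(F)` *with*
#' intercept; sigma0 is the intercept, floored at zero.
#'
#' @param F per-bin median primary fluorescence.
#' @param sigma per-bin robust SD of one secondary dye.
#' @return list with `sigma0` and `beta` (the slope, which underestimates
#'   the spreading coefficient whenever sigma0 > 0).
#' @export
estimate_sigma0 <- function(F, sigma) {
  x <- f_sqrt(F)
  if (stats::sd(x) == 0)
    fs_stop("zero_variance", "all quantile bins have equal primary fluorescence")
  cf <- stats::lm.fit(cbind(1, x), sigma)$coefficients
  list(sigma0 = max(unname(cf[1]), 0), beta = unname(cf[2]))
}

#' Spreading coefficient from adjusted robust SDs
#'
#' Second regression: `f_sqrt(sigma^2 - sigma0^2)` on `f_sqrt(F)` without an
#' intercept (the sigma0 adjustment forces the line through the origin).
#' The coefficient is kept only if the regression F-test is significant at
#' `alpha` and the slope is positive; otherwise it is zeroed with a reason.
#'
#' @param F,sigma per-bin primary medians and secondary robust SDs.
#' @param sigma0 noise floor from [estimate_sigma0()].
#' @param alpha significance level of the F-test.
#' @return list with `coefficient` (zeroed when not retained), `raw_slope`,
#'   `p_value`, `reason` ("" if retained, otherwise "nonsignificant" or
#'   "negative").
#' @export
spreading_coefficient <- function(F, sigma, sigma0, alpha = 0.05) {
  y <- f_sqrt(sigma^2 - sigma0^2)
  x <- f_sqrt(F)
  fit <- stats::lm(y ~ 0 + x)
  sm <- summary(fit)
  slope <- unname(coef(fit)[1])
  fstat <- sm$fstatistic
  p <- if (is.null(fstat) || is.na(fstat[1])) NA_real_
       else if (is.infinite(fstat[1])) 0  # exact fit: perfectly significant
       else stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  if (!is.na(p) && p < alpha && slope > 0)
    list(coefficient = slope, raw_slope = slope, p_value = p, reason = "")
  else if (!is.na(slope) && slope <= 0)
    list(coefficient = 0, raw_slope = slope, p_value = p, reason = "negative")
  else
    list(coefficient = 0, raw_slope = slope, p_value = p, reason = "nonsignificant")
}

#' Build the spillover spreading matrix
#'
#' For every ordered pair (P, C) of dyes, P != C: partition the compensated
#' control of P into quantile bins of its primary values, estimate sigma0
#' for C, then the spreading coefficient. The diagonal is zero.
#'
#' @param X named list (by dye) of compensated matrices (events x dyes),
#'   e.g. the `compensated` element of [refine_until_convergence()].
#' @param alpha F-test significance level.
#' @param adjust_sigma0 set to `FALSE` to skip the noise-floor adjustment
#'   (takes the first regression's slope beta as the coefficient; exposed to
#'   demonstrate the downward bias this induces).
#' @param min_per_bin,ladder passed to [partition_quantiles()].
#' @return list of class `spreading_matrix` with `coef` (d x d, nonnegative,
#'   zero diagonal), `sigma0`, `reason` (character matrix, "" = retained).
#' @export
build_ssm <- function(X, alpha = 0.05, adjust_sigma0 = TRUE,
                      min_per_bin = 32L,
                      ladder = c(256L, 128L, 64L, 32L, 16L, 8L)) {
  dyes <- names(X)
  d <- length(dyes)
  coefm <- matrix(0, d, d, dimnames = list(dyes, dyes))
  s0m <- matrix(NA_real_, d, d, dimnames = list(dyes, dyes))
  reason <- matrix("", d, d, dimnames = list(dyes, dyes))
  for (i in seq_len(d)) {
    M <- X[[i]]
    q <- partition_quantiles(M[, i], M[, -i, drop = FALSE], min_per_bin, ladder)
    for (j in seq_len(d)[-i]) {
      sig <- q$sigma[, dyes[j]]
      s0 <- estimate_sigma0(q$F, sig)
      if (adjust_sigma0) {
        sc <- spreading_coefficient(q$F, sig, s0$sigma0, alpha)
        coefm[i, j] <- sc$coefficient
        reason[i, j] <- sc$reason
      } else {
        coefm[i, j] <- max(s0$beta, 0)
        reason[i, j] <- if (s0$beta > 0) "" else "negative"
      }
      s0m[i, j] <- s0$sigma0
    }
  }
  structure(list(coef = coefm, sigma0 = s0m, reason = reason),
            class = "spreading_matrix")
}

#' @export
print.spreading_matrix <- function(x, ...) {
  cat(sprintf("<spreading_matrix: %d x %d, %d retained coefficients>\n",
              nrow(x$coef), ncol(x$coef), sum(x$reason == "" ) - nrow(x$coef)))
  print(round(x$coef, 4))
  invisible(x)
}

#' Traditional positive/negative-population SSM (comparison oracle)
#'
#' The classical calculation: split each control on its compensated primary
#' values by deterministic 2-means, then
#' `SS = sqrt(sigma_pos^2 - sigma_neg^2) / sqrt(F_pos - F_neg)` with medians
#' for F and robust SDs (P84 - median) for sigma. A negative variance
#' difference zeroes the coefficient with a flag; equal medians flag the
#' pair as inseparable (NA).
#'
#' @param X named list (by dye) of compensated matrices.
#' @return list of class `spreading_matrix` with `coef` and `reason`
#'   (flags: "negative_variance", "inseparable").
#' @export
traditional_ssm <- function(X) {
  dyes <- names(X)
  d <- length(dyes)
  coefm <- matrix(0, d, d, dimnames = list(dyes, dyes))
  reason <- matrix("", d, d, dimnames = list(dyes, dyes))
  for (i in seq_len(d)) {
    v <- X[[i]][, i]
    if (min(v) == max(v)) {
      coefm[i, -i] <- NA_real_; reason[i, -i] <- "inseparable"; next
    }
    km <- stats::kmeans(v, centers = matrix(c(min(v), max(v)), 2, 1))
    pos <- km$cluster == which.max(km$centers)
    fp <- stats::median(v[pos]); fn <- stats::median(v[!pos])
    for (j in seq_len(d)[-i]) {
      if (!is.finite(fp - fn) || fp - fn <= 0) {
        coefm[i, j] <- NA_real_; reason[i, j] <- "inseparable"; next
      }
      rsd <- function(z) stats::quantile(z, 0.84, names = FALSE) - stats::median(z)
      sp <- rsd(X[[i]][pos, j]); sn <- rsd(X[[i]][!pos, j])
      if (sp^2 < sn^2) {
        coefm[i, j] <- 0; reason[i, j] <- "negative_variance"
      } else {
        coefm[i, j] <- sqrt(sp^2 - sn^2) / sqrt(fp - fn)
      }
    }
  }
  structure(list(coef = coefm, sigma0 = NULL, reason = reason),
            class = "spreading_matrix")
}
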