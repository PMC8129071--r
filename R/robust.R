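#' Huber-robust slope of y on x
#'
#' Iteratively reweighted least squares with Huber weights (tuning constant
#' `k` on residuals standardized by a median-absolute-deviation scale),
#' through [MASS::rlm()]. Fluorescence data are heteroskedastic
#' (photon-counting statistics) and contaminated by outliers, which makes
#' M-estimation preferable to ordinary least squares for reading a spillover
#' coefficient off the slope.
#'
#' Exact fits and constant responses are handled before IRLS: when the
#' least-squares residuals are zero to numerical precision the MAD scale
#' collapses and reweighting is meaningless, so the least-squares solution
#' (which is then exact) is returned directly.
#'
#' @param x,y numeric vectors (at least 10 finite pairs; `x` must vary).
#' @param k Huber tuning constant (default 1.345, 95% Gaussian efficiency).
#' @param maxit,tol IRLS iteration cap and relative convergence tolerance.
#' @param warn emit a warning when IRLS does not converge within `maxit`.
#' @return list with `slope`, `intercept`, `converged`.
#' @export
fit_slope_robust <- function(x, y, k = 1.345, maxit = 50L, tol = 1e-8,
                             warn = TRUE) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 10L)
    fs_stop("too_few_events", "need at least 10 finite (x, y) pairs")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0)
    fs_stop("zero_variance", "predictor has zero variance")
  X <- cbind(1, x)
  ls <- stats::lm.fit(X, y)
  scale_ref <- max(stats::mad(y, center = stats::median(y)), stats::sd(y))
  if (stats::mad(ls$residuals) <= 1e-10 * max(scale_ref, 1e-300) ||
      all(abs(ls$residuals) < 1e-10 * max(mean(abs(y)), 1e-300) + 1e-280)) {
    cf <- ls$coefficients
    return(list(slope = unname(cf[2]), intercept = unname(cf[1]), converged = TRUE))
  }
  fit <- withCallingHandlers(
    MASS::rlm(X, y, psi = MASS::psi.huber, k = k, scale.est = "MAD",
              maxit = maxit, acc = tol),
    warning = function(w) invokeRestart("muffleWarning"))
  if (!fit$converged && warn)
    fs_warn("irls_nonconvergence",
            sprintf("IRLS did not converge in %d iterations", maxit))
  cf <- fit$coefficients
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       converged = fit$converged)
}
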