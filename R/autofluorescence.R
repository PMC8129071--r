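# Autofluorescence as an endogenous dye.
#
# Cellular autofluorescence behaves like spillover from a dye no one added:
# it has a reproducible spectrum across detectors and a per-cell intensity,
# but no distinct positive population. Because the spillover estimator does
# not need positive/negative populations, an unstained control can be folded
# into the control set as the single-color control of an extra dye ("AF")
# whose primary channel is a detector not used by any real dye, after which
# compensation removes autofluorescence like any other spillover.

#' Choose the autofluorescence channel
#'
#' Automatic choice: the non-scatter detector with the highest median signal
#' in the unstained control among detectors not already assigned as a dye
#' primary (the most autofluorescent free channel gives the best leverage).
#' An explicit name is honored after validation.
#'
#' @param unstained gated [event_table()] of the unstained control.
#' @param used_primaries detector names already assigned to dyes.
#' @param channel "AUTO" or an explicit detector name.
#' @return detector name.
#' @export
select_af_channel <- function(unstained, used_primaries, channel = "AUTO") {
  free <- setdiff(fluor_detectors(unstained), used_primaries)
  if (length(free) == 0L)
    fs_stop("no_free_detector", "no detector left free for autofluorescence")
  if (toupper(channel) != "AUTO") {
    if (!(channel %in% fluor_detectors(unstained)))
      fs_stop("detector_not_found", paste("unknown detector:", channel))
    if (!(channel %in% free))
      fs_stop("detector_in_use",
              paste("detector", channel, "is already a dye primary"))
    return(channel)
  }
  med <- apply(fluor_values(unstained, free), 2, stats::median)
  free[which.max(med)]
}

#' Fold the unstained control into a control set as an extra dye
#'
#' Appends the unstained control as dye `"AF"` (last) with the chosen
#' autofluorescence channel as its primary detector; all downstream spillover
#' estimation and refinement then treat autofluorescence as one more dye.
#' Requires a free detector, so the augmented dye count d + 1 must not
#' exceed the detector count.
#'
#' @param cs a [control_set()] with an unstained control.
#' @param channel "AUTO" or an explicit free detector name.
#' @param name dye name for the autofluorescence row.
#' @return a [control_set()] with d + 1 dyes (and no unstained slot).
#' @export
augment_with_af <- function(cs, channel = "AUTO", name = "AF") {
  if (is.null(cs$unstained))
    fs_stop("no_unstained", "control set has no unstained control")
  if (name %in% names(cs$controls))
    fs_stop("duplicate_dye", paste("dye name already in use:", name))
  used <- cs$primary[!is.na(cs$primary)]
  af_ch <- select_af_channel(cs$unstained, used, channel)
  controls <- c(cs$controls, stats::setNames(list(cs$unstained), name))
  primary <- c(cs$primary, stats::setNames(af_ch, name))
  control_set(controls, primary, unstained = NULL)
}

#' Residual slopes of real dyes versus autofluorescence
#'
#' Diagnostic for autofluorescence removal: the compensation-error slope of
#' each compensated dye signal against an autofluorescence reference (the
#' compensated AF dye when augmentation was used, or the raw unstained
#' signal in the AF channel when it was not). Near-zero slopes mean
#' autofluorescence no longer leaks into the dye channels. When `transform`
#' is supplied (e.g. the final transform of [refine_until_convergence()]),
#' slopes are measured exactly as the refinement measures its errors:
#' Huber regression in bi-exponential scale, chord-mapped back to linear.
#'
#' @param X compensated events x dyes matrix for the unstained control.
#' @param af_ref numeric vector: the autofluorescence reference signal.
#' @param dyes dye columns to report (default: all columns of `X`).
#' @param transform optional [fit_biexp()] object; its `"AF"` width is used
#'   for the reference signal (falling back to 1).
#' @param k Huber tuning constant.
#' @return named numeric vector of slopes.
#' @export
af_residual_slopes <- function(X, af_ref, dyes = colnames(X),
                               transform = NULL, k = 1.345) {
  wref <- if (!is.null(transform) && "AF" %in% names(transform))
    transform[["AF"]] else 1
  vapply(dyes, function(j) {
    wj <- if (is.null(transform)) NULL else transform[[j]]
    error_slope(af_ref, X[, j],
                if (is.null(transform)) NULL else wref, wj, k)
  }, 1.0)
}
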