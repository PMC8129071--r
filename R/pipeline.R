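# End-to-end orchestration: gate -> initial estimate -> refinement -> SSM.

#' Fit a spillover matrix from a control set
#'
#' Runs the full pipeline on a [control_set()]: optional autofluorescence
#' augmentation, automatic scatter gating of every control, primary-channel
#' resolution, the initial robust-regression estimate, and iterative
#' refinement to convergence.
#'
#' @param cs a [control_set()].
#' @param config a [spillover_config()].
#' @param gate gate each control on scatter first (disable for data that is
#'   already gated or has no scatter channels).
#' @param autofluorescence fold the unstained control in as an extra dye.
#' @param af_channel "AUTO" or an explicit free detector.
#' @param gate_args extra arguments passed to [compute_gate()].
#' @return list with `spillover`, `initial`, `trace`, `status`,
#'   `iterations`, `compensated`, `errors`, `primary`, `gates` and (when
#'   autofluorescence is used) `af_channel`.
#' @export
fit_spillover <- function(cs, config = spillover_config(), gate = TRUE,
                          autofluorescence = FALSE, af_channel = "AUTO",
                          gate_args = list()) {
  if (autofluorescence) {
    if (is.null(cs$unstained))
      fs_stop("no_unstained",
              "autofluorescence removal requires an unstained control")
    cs <- augment_with_af(cs, af_channel)
  }
  gates <- list()
  gated <- list()
  for (dye in names(cs$controls)) {
    et <- cs$controls[[dye]]
    if (gate) {
      g <- tryCatch(do.call(compute_gate, c(list(et), gate_args)),
                    flowspill_error = function(e)
                      fs_stop("gating_failed",
                              sprintf("gating failed for control '%s': %s",
                                      dye, conditionMessage(e))))
      gates[[dye]] <- g
      et <- g$events
    }
    gated[[dye]] <- et
  }
  primary <- cs$primary
  for (dye in names(gated))
    primary[dye] <- resolve_primary(gated[[dye]], primary[[dye]])
  dets <- fluor_detectors(gated[[1]])
  Y <- lapply(gated, fluor_values, detectors = dets)
  S0 <- initial_spillover(Y, primary, config$huber_k)
  res <- refine_until_convergence(Y, S0, config)
  out <- c(res, list(initial = S0, primary = primary, gates = gates,
                     gated = gated))
  if (autofluorescence) out$af_channel <- unname(primary["AF"])
  out
}

#' Run the spillover pipeline from files
#'
#' Reads a control index and its FCS files, fits the spillover matrix and
#' writes `spillover.csv`, `trace.tsv` and `gate_vertices.csv` into the
#' output directory.
#'
#' @param index path to the control-index CSV.
#' @param dir directory containing the FCS files.
#' @param out_dir output directory.
#' @param ... passed to [fit_spillover()].
#' @return the [fit_spillover()] result, invisibly.
#' @export
run_spillover_pipeline <- function(index, dir = dirname(index),
                                   out_dir = ".", ...) {
  cs <- read_control_set(index, dir)
  res <- fit_spillover(cs, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_spillover_csv(unclass(res$spillover), file.path(out_dir, "spillover.csv"))
  write_trace(res$trace, file.path(out_dir, "trace.tsv"))
  if (length(res$gates)) {
    verts <- do.call(rbind, lapply(names(res$gates), function(dye) {
      p <- res$gates[[dye]]$polygon
      cbind(data.frame(dye = dye), p)
    }))
    utils::write.table(verts, file.path(out_dir, "gate_vertices.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(res)
}

#' Run the spreading-matrix pipeline from files
#'
#' Reads the controls and a spillover matrix CSV (for example the one
#' written by [run_spillover_pipeline()]), compensates the gated controls
#' and writes `ssm.csv` plus a sidecar `ssm_flags.tsv` with the zero-reason
#' annotations.
#'
#' @param index path to the control-index CSV.
#' @param spillover_csv path to the spillover matrix CSV.
#' @param dir directory containing the FCS files.
#' @param out_dir output directory.
#' @param alpha F-test significance level.
#' @param gate gate controls before compensating.
#' @return the [build_ssm()] result, invisibly.
#' @export
run_spread_pipeline <- function(index, spillover_csv, dir = dirname(index),
                                out_dir = ".", alpha = 0.05, gate = TRUE) {
  cs <- read_control_set(index, dir)
  S <- read_spillover_csv(spillover_csv)
  if (!setequal(rownames(S), names(cs$controls)))
    fs_stop("panel_mismatch",
            "spillover matrix dyes do not match the control index")
  S <- S[names(cs$controls), , drop = FALSE]
  pcols <- apply(S, 1, which.max)
  S <- new_spillover(S, pcols)
  X <- list()
  for (dye in names(cs$controls)) {
    et <- cs$controls[[dye]]
    if (gate) et <- compute_gate(et)$events
    X[[dye]] <- compensate(et, S)
  }
  ssm <- build_ssm(X, alpha = alpha)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_spillover_csv(ssm$coef, file.path(out_dir, "ssm.csv"))
  flags <- which(ssm$reason != "", arr.ind = TRUE)
  flag_df <- data.frame(
    primary = rownames(ssm$reason)[flags[, 1]],
    secondary = colnames(ssm$reason)[flags[, 2]],
    reason = ssm$reason[flags])
  utils::write.table(flag_df, file.path(out_dir, "ssm_flags.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(ssm)
}
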