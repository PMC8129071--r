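# Synthetic single-color controls with known ground truth.
#
# The generator reproduces the statistical structure the estimators assume:
# row-normalized emission spectra (Gaussian bumps over detector index),
# photon-counting-like heteroskedastic detector noise (variance a*|mean|+b),
# dye intensity distributions with and without distinct positive
# populations, an autofluorescence spectrum with per-cell log-normal
# intensity, and FSC/SSC scatter with a debris cluster near the origin.
# Scatter clusters are filled ellipses (uniform radial core, Gaussian edge):
# cell and bead populations form plateau-like, sharply bounded density
# blobs, which a Gaussian would misrepresent (its density falls off so fast
# that a fixed-fraction density threshold encloses only ~2/3 of the mass).

#' Specification of a synthetic control panel
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: 8 dyes on 8 detectors, 20,000 events per control, bimodal
#' intensity (50% unstained events, positive population log-normal with
#' median 1e4 and sdlog 1), shot-noise gain a = 0.05 x positive-median scale
#' and electronic noise floor b = 1e4 (robust SD 100 at zero light), 20%
#' debris, no autofluorescence.
#'
#' @param d,c number of dyes and detectors (d <= c).
#' @param n events per control.
#' @param intensity per-dye intensity model, recycled: "bimodal" (negative
#'   population + distinct log-normal positive), "smear" (gamma-distributed
#'   continuum with no distinct positive population), or "dim" (bimodal at
#'   1/20 the scale).
#' @param pos_scale median of the positive population (arbitrary
#'   fluorescence units).
#' @param pos_sdlog log-scale SD of the positive population.
#' @param neg_fraction fraction of unstained (x = 0) events in bimodal/dim
#'   controls.
#' @param noise_a shot-noise gain: detector variance is
#'   `noise_a * |mean| + noise_b`.
#' @param noise_b electronic noise floor (variance at zero light).
#' @param spectrum_width Gaussian bump width of the emission spectra, in
#'   detector-index units.
#' @param af_amplitude autofluorescence amplitude in the brightest AF
#'   detector (0 disables autofluorescence).
#' @param af_sdlog log-scale SD of the per-cell autofluorescence factor.
#' @param af_peak detector index where the AF spectrum peaks.
#' @param af_width AF spectrum bump width (broader than dye spectra).
#' @param debris_fraction fraction of debris events.
#' @param scatter list of scatter-model parameters (cluster centers,
#'   semiaxes, edge SD as a fraction of the semiaxes).
#' @param seed integer seed; all generation is reproducible given the spec.
#' @return list of class `panel_spec`, including the ground-truth spillover
#'   matrix `S_true` (rows normalized to 1 at the primary detector) and the
#'   normalized AF spectrum `af_spectrum`.
#' @export
synthetic_panel_spec <- function(d = 8L, c = d, n = 20000L,
                                 intensity = "bimodal",
                                 pos_scale = 1e4, pos_sdlog = 1,
                                 neg_fraction = 0.5,
                                 noise_a = 0.05 * pos_scale, noise_b = 1e4,
                                 spectrum_width = 0.8,
                                 af_amplitude = 0, af_sdlog = 0.6,
                                 af_peak = c, af_width = 2,
                                 debris_fraction = 0.2,
                                 scatter = NULL, seed = 1L) {
  if (d > c) fs_stop("bad_spec", "need at least as many detectors as dyes")
  if (debris_fraction < 0 || debris_fraction >= 1)
    fs_stop("bad_spec", "debris_fraction must be in [0, 1)")
  if (noise_a < 0 || noise_b < 0) fs_stop("bad_spec", "noise terms must be >= 0")
  intensity <- rep_len(intensity, d)
  if (!all(intensity %in% c("bimodal", "smear", "dim")))
    fs_stop("bad_spec", "unknown intensity model")
  if (is.null(scatter)) scatter <- list(
    cell_center = c(1e5, 6e4), cell_radii = c(2.5e4, 1.5e4),
    debris_center = c(6e3, 3e3), debris_radii = c(4e3, 2.5e3),
    edge_sd_frac = 0.03)
  dyes <- paste0("Dye", seq_len(d))
  detectors <- paste0("FL", seq_len(c), "-A")
  primaries <- seq_len(d)  # spare detectors (if any) sit above the dyes
  S_true <- t(vapply(seq_len(d), function(i)
    exp(-(seq_len(c) - primaries[i])^2 / (2 * spectrum_width^2)),
    numeric(c)))
  S_true <- S_true / apply(S_true, 1, max)  # primary entry exactly 1
  dimnames(S_true) <- list(dyes, detectors)
  af_spectrum <- exp(-(seq_len(c) - af_peak)^2 / (2 * af_width^2))
  af_spectrum <- af_spectrum / max(af_spectrum)
  names(af_spectrum) <- detectors
  structure(list(
    d = d, c = c, n = as.integer(n), intensity = intensity,
    pos_scale = pos_scale, pos_sdlog = pos_sdlog, neg_fraction = neg_fraction,
    noise_a = noise_a, noise_b = noise_b,
    af_amplitude = af_amplitude, af_sdlog = af_sdlog,
    af_spectrum = af_spectrum, debris_fraction = debris_fraction,
    scatter = scatter, seed = as.integer(seed),
    dyes = dyes, detectors = detectors,
    primaries = stats::setNames(detectors[primaries], dyes),
    S_true = new_spillover(S_true, stats::setNames(primaries, dyes))),
    class = "panel_spec")
}

# scatter cluster: a broad, gently domed shoulder (radial density
# 1 - 0.15 r^4 on the unit disk) carrying 95% of the mass, plus a 5%-mass
# central Gaussian cap (sd 0.25 radii) that marks a single dominant density
# mode, with a soft Gaussian edge. Real cell/bead populations show exactly
# this structure: a clear mode on a fat shoulder with a thin dim rim.
sample_blob <- function(n, center, radii, edge_sd_frac,
                        cap_mass = 0.05, cap_sd = 0.25, dome = 0.15) {
  ncap <- rbinom(1, n, cap_mass)
  r <- numeric(0)
  while (length(r) < n - ncap) {  # rejection sampling from the domed disk
    cand <- sqrt(runif(2 * n))
    r <- c(r, cand[runif(2 * n) < (1 - dome * cand^4)])
  }
  r <- r[seq_len(n - ncap)]
  theta <- runif(n - ncap, 0, 2 * pi)
  u <- rbind(cbind(r * cos(theta), r * sin(theta)),
             matrix(rnorm(2 * ncap, 0, cap_sd), ncol = 2))
  u <- u[sample(n), , drop = FALSE]
  cbind(center[1] + u[, 1] * radii[1] + rnorm(n, 0, edge_sd_frac * radii[1]),
        center[2] + u[, 2] * radii[2] + rnorm(n, 0, edge_sd_frac * radii[2]))
}

# per-dye true intensity draws (0 for debris handled by the caller)
sample_intensity <- function(model, n, spec) {
  switch(model,
    bimodal = ifelse(runif(n) < spec$neg_fraction, 0,
                     rlnorm(n, log(spec$pos_scale), spec$pos_sdlog)),
    dim = ifelse(runif(n) < spec$neg_fraction, 0,
                 rlnorm(n, log(spec$pos_scale / 20), spec$pos_sdlog)),
    smear = rgamma(n, shape = 0.7, scale = spec$pos_scale))
}

#' Generate one synthetic single-color control
#'
#' Observed fluorescence is `x * S_true[dye, ] + af * spectrum + noise`,
#' with per-detector noise SD `sqrt(a |mean| + b)`; scatter values (cell
#' blob or debris blob near the origin) are appended as FSC-A/SSC-A. Debris
#' events carry zero dye signal and reduced autofluorescence.
#'
#' @param spec a [synthetic_panel_spec()].
#' @param dye a dye name from the spec, or `"unstained"`.
#' @param seed seed for this control; the default derives one per control
#'   from `spec$seed`.
#' @return list with `events` (an [event_table()]), `x` (true dye signal per
#'   event), `af` (autofluorescence factor) and `debris` (logical label).
#' @export
generate_control <- function(spec, dye,
                             seed = spec$seed + match(dye, c(spec$dyes, "unstained"))) {
  if (!dye %in% c(spec$dyes, "unstained"))
    fs_stop("bad_spec", paste("unknown dye:", dye))
  set.seed(seed)
  n <- spec$n
  debris <- runif(n) < spec$debris_fraction
  x <- numeric(n)
  if (dye != "unstained") {
    model <- spec$intensity[match(dye, spec$dyes)]
    x[!debris] <- sample_intensity(model, sum(!debris), spec)
  }
  af <- if (spec$af_amplitude > 0)
    spec$af_amplitude * rlnorm(n, 0, spec$af_sdlog) * ifelse(debris, 0.2, 1)
  else numeric(n)
  spectrum <- if (dye != "unstained") unclass(spec$S_true)[dye, ] else
    numeric(spec$c)
  m <- outer(x, spectrum) + outer(af, spec$af_spectrum)
  noise_sd <- sqrt(spec$noise_a * abs(m) + spec$noise_b)
  y <- m + matrix(rnorm(length(m)), nrow(m)) * noise_sd
  colnames(y) <- spec$detectors
  sc <- spec$scatter
  xy <- matrix(0, n, 2)
  if (any(!debris)) xy[!debris, ] <- sample_blob(sum(!debris), sc$cell_center,
                                                 sc$cell_radii, sc$edge_sd_frac)
  if (any(debris)) xy[debris, ] <- sample_blob(sum(debris), sc$debris_center,
                                               sc$debris_radii, sc$edge_sd_frac)
  xy <- pmax(xy, 1)
  colnames(xy) <- c("FSC-A", "SSC-A")
  list(events = event_table(cbind(xy, y)), x = x, af = af, debris = debris)
}

#' Generate a complete synthetic control panel
#'
#' One single-color control per dye plus an unstained control, with all
#' ground truth needed by the test suites: the true spillover matrix, and
#' (for square panels) the spreading matrix and noise floor implied by the
#' noise model. Under perfect compensation the dye-space variance induced
#' by the control for dye P in dye C is
#' `sum_k (a x S[P,k] + b) (Sinv[k,C])^2`, so the implied coefficients are
#' `SS[P,C] = sqrt(a sum_k S[P,k] Sinv[k,C]^2)` and
#' `sigma0[C] = sqrt(b sum_k Sinv[k,C]^2)`.
#'
#' @param spec a [synthetic_panel_spec()].
#' @return list with `controls` (a [control_set()] with explicit primaries
#'   and the unstained control), `S_true`, `SS_true`, `sigma0_true` and
#'   `truth` (per-control ground-truth draws).
#' @export
generate_panel <- function(spec) {
  truth <- list()
  controls <- list()
  for (i in seq_along(spec$dyes)) {
    g <- generate_control(spec, spec$dyes[i], seed = spec$seed + i)
    controls[[spec$dyes[i]]] <- g$events
    truth[[spec$dyes[i]]] <- g[c("x", "af", "debris")]
  }
  gu <- generate_control(spec, "unstained", seed = spec$seed + spec$d + 1L)
  truth$unstained <- gu[c("x", "af", "debris")]
  SS_true <- sigma0_true <- NULL
  if (spec$c == spec$d) {
    Sm <- unclass(spec$S_true); attr(Sm, "primary") <- NULL
    Sinv <- solve(Sm)
    SS_true <- matrix(0, spec$d, spec$d, dimnames = list(spec$dyes, spec$dyes))
    for (p in seq_len(spec$d)) for (cc in seq_len(spec$d)) {
      if (p == cc) next
      SS_true[p, cc] <- sqrt(spec$noise_a * sum(Sm[p, ] * Sinv[, cc]^2))
    }
    sigma0_true <- sqrt(spec$noise_b * colSums(Sinv^2))
    names(sigma0_true) <- spec$dyes
  }
  list(controls = control_set(controls, spec$primaries, gu$events),
       S_true = spec$S_true, SS_true = SS_true, sigma0_true = sigma0_true,
       truth = truth)
}

#' Simulate spreading-model events directly
#'
#' Draws (F, C) pairs from the spreading model itself: a negative population
#' residing close to zero primary fluorescence (as compensated single-color
#' controls always contain) plus a log-normal positive population; secondary
#' values are normal with `sd = sqrt(ss^2 max(F, 0) + sigma0^2)`. The
#' near-zero population is what pins the noise-floor intercept of the first
#' SSM regression. Used to validate the SSM estimator against exact ground
#' truth.
#'
#' @param n number of events.
#' @param ss true spreading coefficient.
#' @param sigma0 true noise floor.
#' @param neg_fraction fraction of events in the negative population.
#' @param neg_sd spread of the negative population's compensated primary
#'   values (defaults to the noise floor, its physical source).
#' @param f_meanlog,f_sdlog log-normal parameters of the positive F.
#' @param seed integer seed.
#' @return data.frame with columns `F` and `C`.
#' @export
simulate_spread_events <- function(n, ss, sigma0, neg_fraction = 0.5,
                                   neg_sd = max(sigma0, 5),
                                   f_meanlog = log(5000), f_sdlog = 1.2,
                                   seed = 1L) {
  set.seed(seed)
  neg <- runif(n) < neg_fraction
  F <- ifelse(neg, rnorm(n, 0, neg_sd), rlnorm(n, f_meanlog, f_sdlog))
  C <- rnorm(n, 0, sqrt(ss^2 * pmax(F, 0) + sigma0^2))
  data.frame(F = F, C = C)
}

#' Write a synthetic panel to disk as FCS files plus index
#'
#' Emits one FCS 3.1 file per control (plus the unstained control), a
#' control-index CSV and a ground-truth spillover CSV, so the command-line
#' pipeline can be exercised end to end from files.
#'
#' @param spec a [synthetic_panel_spec()].
#' @param dir output directory (created if needed).
#' @return invisible list with the generated panel and file paths.
#' @export
write_fixture_panel <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- generate_panel(spec)
  files <- character(0)
  rows <- list()
  for (dye in names(panel$controls$controls)) {
    f <- paste0(dye, ".fcs")
    write_fcs(panel$controls$controls[[dye]], file.path(dir, f))
    rows[[length(rows) + 1L]] <- data.frame(
      file = f, dye = dye, primary_detector = panel$controls$primary[[dye]],
      unstained = 0L)
    files <- c(files, f)
  }
  if (!is.null(panel$controls$unstained)) {
    write_fcs(panel$controls$unstained, file.path(dir, "unstained.fcs"))
    rows[[length(rows) + 1L]] <- data.frame(
      file = "unstained.fcs", dye = "unstained", primary_detector = "AUTO",
      unstained = 1L)
  }
  idx <- do.call(rbind, rows)
  utils::write.table(idx, file.path(dir, "index.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  write_spillover_csv(unclass(panel$S_true), file.path(dir, "spillover_true.csv"))
  invisible(list(panel = panel, dir = dir, index = file.path(dir, "index.csv")))
}
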