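# Shared fixture builders; everything is generated in code under fixed seeds.

# small, fast panel for unit tests (no debris, no scatter interference)
tiny_panel <- function(d = 3, n = 2000, seed = 42, ...) {
  generate_panel(synthetic_panel_spec(d = d, n = n, debris_fraction = 0,
                                      seed = seed, ...))
}

# fluorescence matrices of a panel's controls, in detector order
panel_fluor <- function(panel) {
  lapply(panel$controls$controls, fluor_values)
}

# noise-free events for one dye at given true intensity levels
noise_free_events <- function(S, dye_index, x_levels) {
  Sm <- unclass(S); attr(Sm, "primary") <- NULL
  outer(x_levels, Sm[dye_index, ])
}

# brute-force per-event compensation-error oracle: for each control i,
# generate noise-free average events at the given levels, compensate with U,
# and read E[i, j] = p_j / x_i off the (constant) per-event ratios.
# keep_diagonal = TRUE retains E[i, i] = p_i / x_i instead of zeroing it.
per_event_error_oracle <- function(U, S_true, x_levels = c(1e2, 1e3, 1e4),
                                   keep_diagonal = FALSE) {
  d <- nrow(S_true)
  Um <- unclass(U); attr(Um, "primary") <- NULL
  E <- matrix(0, d, d, dimnames = dimnames(Um)[c(1, 1)])
  for (i in seq_len(d)) {
    Y <- noise_free_events(S_true, i, x_levels)
    X <- Y %*% solve(Um)
    ratios <- sweep(X, 1, x_levels, "/")
    ratios[, i] <- ratios[, i] - 1  # p_i = x_i-compensated minus truth
    stopifnot(max(apply(ratios, 2, stats::sd)) < 1e-10)  # level-invariant
    E[i, ] <- colMeans(ratios)
    if (!keep_diagonal) E[i, i] <- 0
  }
  E
}

# deterministic row-normalized perturbation of a spillover matrix
perturb_spillover <- function(S, magnitude = 1e-3, seed = 1) {
  set.seed(seed)
  Sm <- unclass(S); pc <- attr(S, "primary"); attr(Sm, "primary") <- NULL
  delta <- matrix(stats::rnorm(length(Sm), 0, magnitude), nrow(Sm))
  delta[cbind(seq_len(nrow(Sm)), pc)] <- 0  # primary entries stay exactly 1
  new_spillover(Sm + delta, pc)
}
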