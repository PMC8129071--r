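# flowspill

Spillover estimation for multicolor flow cytometry, without
positive/negative population gymnastics.

Every fluorophore spills signal into detectors other than its own, and
compensation — removing that spillover — is the first analysis step for any
multicolor panel. The classical calculation reads each spillover coefficient
from the median difference between a positive and a negative population in a
single-color control, which breaks down precisely where modern panels hurt:
dim dyes, rare positives, smeared continua, autofluorescent cells.

`flowspill` computes the `d x c` spillover matrix `S` (rows = dyes,
columns = detectors, row-normalized with `S[i, h_i] = 1` at the primary
detector) from single-color controls in three automated stages:

1. **Gating.** The cell/bead population is isolated on FSC/SSC by
   density-based tessellation: trim 1%–99%, locate kernel-density maxima,
   assign events to Voronoi tiles of the maxima, drop the low-scatter debris
   peak, and gate on the convex hull of the high-density core
   (`compute_gate()`).
2. **Robust regression.** Since `x S = y` on average, each coefficient is
   the slope of secondary-vs-primary signal over the gated events, fitted by
   Huber M-estimation (`k = 1.345`) to tolerate heteroskedastic
   photon-counting noise and outliers (`initial_spillover()`).
3. **Iterative refinement.** Compensating with an erroneous matrix
   `U = S + T` leaves residual slopes `E` in the compensated controls, and
   for the average event `T = -E U` exactly. The loop measures `E`, applies
   `S <- rownorm(S + E S)`, switches to a bi-exponential measurement scale
   below max|E| = 1e-2, damps updates to 10% if oscillations are detected,
   and stops at max|E| < 1e-4 (`refine_until_convergence()`).

Autofluorescence can be compensated out by treating an unstained control as
an extra endogenous dye on a free detector (`augment_with_af()`). A second
estimator computes the **spillover spreading matrix** — the incremental
robust SD induced in detector C per unit √fluorescence of P after
compensation, `sigma^2 = SS^2 F + sigma0^2` — by quantile partitioning and
two regressions with a noise-floor adjustment (`build_ssm()`).

A synthetic single-color-control generator with exact ground truth
(`generate_panel()`), a minimal FCS 3.0/3.1 reader and fixture writer, and a
CLI (`inst/scripts/flowspill`) round out the package.

## Worked example

```r
library(flowspill)

spec  <- synthetic_panel_spec(d = 4, n = 12000, seed = 7)  # known ground truth
panel <- generate_panel(spec)
fit   <- fit_spillover(panel$controls)   # gate -> regress -> refine
fit$spillover
#> <spillover_matrix: 4 dyes x 4 detectors>
#>       FL1-A  FL2-A  FL3-A  FL4-A
#> Dye1 1.0000 0.4359 0.0414 0.0001
#> Dye2 0.4360 1.0000 0.4316 0.0440
#> Dye3 0.0431 0.4308 1.0000 0.4361
#> Dye4 0.0008 0.0430 0.4423 1.0000
tail(fit$trace[, c("iteration", "scale", "sd_error", "max_error")], 3)
#>    iteration scale     sd_error    max_error
#> 10         9 biexp 5.852947e-05 1.376711e-04
#> 11        10 biexp 4.874336e-05 1.172077e-04
#> 12        11 biexp 4.059333e-05 9.977871e-05
```

The run converged after 12 iterations: the maximum residual compensation
slope across all controls fell below 1e-4, i.e. no secondary dye retains a
detectable trend against any primary in the compensated controls. Rows are
the dyes' normalized emission fingerprints — here each dye spills ~0.43 into
its spectral neighbors and ~0.04 two detectors away, matching the generating
spectra to 0.027 (the residual reflects the panel's deliberately harsh noise
model). The spreading matrix from the same compensated controls:

```r
round(build_ssm(fit$compensated)$coef, 3)
#>        Dye1   Dye2   Dye3   Dye4
#> Dye1  0.000 30.107 13.993  5.756
#> Dye2 24.840  0.000 32.403 11.861
#> Dye3 11.629 31.667  0.000 25.069
#> Dye4  5.832 13.314 30.167  0.000
```

Entry (P, C) is the robust-SD increase induced in dye C per unit
√fluorescence of dye P — the panel-design cost of each pairing: adjacent
(heavily overlapping) dyes spread ~30 units, distant pairs ~6.

Command-line equivalent over FCS files:

```sh
Rscript inst/scripts/flowspill fixtures --out panel --dyes 4 --events 12000 --seed 7
Rscript inst/scripts/flowspill spillover --index panel/index.csv --out results
Rscript inst/scripts/flowspill spread --index panel/index.csv \
    --spillover results/spillover.csv --out results
```

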