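# bandinfer

Bayesian inference of spatial-competition parameters from a **single binary
snapshot** of a sessile community.

Vegetation and other sessile communities — seagrass meadows, mussel beds,
tiger bush — self-organise into striking regular bands wherever short-range
facilitation is paired with longer-range, directionally biased competition
(hydrological scouring down-current, ground-water depletion down-slope). A
single aerial photograph of such a pattern, digitised to an occupied/empty
lattice, contains quantitative information about the process that produced
it. bandinfer extracts that information: it fits a probabilistic
cellular-automaton model to one snapshot, with full parameter uncertainty,
and needs no time series.

## Model and method

Each lattice site is occupied (1) or empty (0) and updates synchronously:

* birth at empty sites at rate `lam * [k1 * S]`, with `k1` a Gaussian growth
  kernel of standard deviation `sigma1` (local facilitation); `lam` is fixed
  to 1 by rescaling time,
* death at occupied sites at rate `c * [k2 * S]`, with `k2` a Gaussian
  competition kernel of standard deviation `sigma2`, displaced by distance
  `r` at angle `theta` (directional long-range competition).

Bands form perpendicular to `theta` with spacing near `2r`. The estimable
parameters are `Theta = (sigma1^2, sigma2^2, c, r, theta)`.

The likelihood of a snapshot under the full process is intractable, so the
package builds a *synthetic likelihood* from the expected rate of change of
the pair-correlation structure. For pair types `XY` in {00, 01, 11} and
Euclidean distances `d = 1..k`, the statistic

    xi_XY(d) = sum over single-site events of (event rate) x (change in N_XY(d))

is the expected instantaneous drift of the ordered pair count `N_XY(d)`. A
stationary pattern has `xi = 0` in expectation, so deviations from zero
measure how badly a parameter vector explains the data. Treating each
statistic as zero-mean normal with variance `tau^2 * N(d)^2` gives

    log l(Theta) = - sum_i [ log(2 pi tau_i^2)/2 + xi_i^2 / (2 tau_i^2) ]

which costs only two kernel convolutions per evaluation once the data
lattice's neighbour-count fields are precomputed. The posterior over `Theta`
is sampled by adaptive component-wise random-walk Metropolis–Hastings with
weakly informative priors measured from the band geometry of the snapshot
itself (wavelength, band and gap widths). The forward simulator, the
variance calibration for `tau^2`, and posterior-predictive simulation are
included; correctness of the core statistics is pinned to an independent
brute-force oracle that recounts all pairs after every possible single-site
flip.

## Worked example

Simulate a banded snapshot in the strong-banding regime, then recover the
generating parameters from that single lattice:

```r
library(bandinfer)

gen  <- model_params(sigma1 = 0.6, sigma2 = 2, c = 1, r = 10, theta = 1.5)
snap <- simulate_pca(gen, n_rows = 100, n_cols = 100, n_steps = 1000, seed = 42)
snap
#> binary_lattice: 100 x 100, periodic boundary, occupancy 0.389

estimate_band_metrics(snap)
#> band_metrics: wavelength 21.00, band 9.75, gap 10.55, orientation 1.48 rad

fit <- fit_snapshot(snap, n_burnin = 5000, n_samples = 50000, seed = 42)
summary(fit)
#> Posterior summary (50000 draws, 95% equal-tailed CI)
#>  parameter    mode    mean     sd ci_lower ci_upper acceptance
#>  sigma1_sq  0.2822  0.2910 0.0386   0.2460   0.3824     0.1933
#>  sigma2_sq  5.3081  5.1636 0.7675   3.2865   6.3105     0.2951
#>          c  0.6752  0.7081 0.0971   0.5842   0.9241     0.2247
#>          r 10.5338 10.7484 1.0731   8.6107  13.4012     0.1890
#>      theta  1.2968  1.8636 0.9422   1.1057   5.0053     0.2011
#>     sigma1  0.5303  0.5383 0.0347   0.4960   0.6184         NA
#>     sigma2  2.3114  2.2656 0.1757   1.8129   2.5121         NA
#> theta modes: 1.822, 5.089, 4.21
```

Read: the band geometry alone pins the wavelength at ~21 lattice units
(twice the competition offset). The fit then recovers the offset itself —
`r` has its mode at 10.5 with a 95% interval (8.6, 13.4) bracketing the
generating value 10 — and places the competition direction near 1.3-1.8 or
its half-turn mirror near 4.2-5.1: a single static pattern cannot
distinguish a kill zone upstream from one downstream, so the direction
marginal genuinely carries two mirror modes. The growth-kernel variance
interval (0.25, 0.38) contains the generating 0.36; the competition
strength and width are recovered less sharply, and their intervals inherit
a known systematic from the synchronous time discretisation, discussed in
the vignette (`vignettes/snapshot-inference.Rmd`).

Posterior-predictive checking, with lattices simulated from posterior
draws:

```r
pp <- posterior_predict(fit, n_draws = 6, n_steps = 400, seed = 42)
pp
#> posterior_predictive: 6 simulated lattices
#>   P11 envelope covers observed at 50% of distances
```

Observed snapshots are read with `read_lattice()` (plain-text 0/1 grids or
thresholded grayscale PNG) and fitted the same way; `run_pipeline()` drives
the whole workflow from a YAML config, and `inst/cli/bandinfer.R` exposes
simulate / stats / xi / calibrate-tau / fit / predict subcommands for shell
use.

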