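---
title: "Inferring spatial competition from a single banded snapshot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring spatial competition from a single banded snapshot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

bandinfer estimates the parameters of a spatial birth–death process from one
binary occupancy snapshot — the situation faced with an aerial photograph of
a seagrass meadow, a mussel bed, or tiger bush, where regular banding is
visible but no time series exists. This vignette is the package's own account
of the model, the synthetic likelihood, the numerical choices, and what the
validation on simulated data does and does not establish.

## The model

The community lives on a square lattice; each site is occupied (1) or empty
(0). Two Gaussian kernels drive the dynamics:

* a growth kernel `k1` with standard deviation `sigma1`, centred on the
  focal site: empty sites become occupied at rate
  `lam * [k1 * S]`, the kernel-weighted density of occupied neighbours
  (local facilitation);
* a competition kernel `k2` with standard deviation `sigma2`, displaced
  from the focal site by distance `r` at angle `theta`: occupied sites die
  at rate `c * [k2 * S]` (directional long-range competition, e.g.
  hydrological scouring down-current of a dense patch).

`lam` is fixed at 1: a single snapshot carries no absolute time scale, so
time is rescaled to make the birth rate unity, and lattice cells are unit
squares. The estimable parameters are `(sigma1^2, sigma2^2, c, r, theta)`.

Updates are synchronous: every site flips independently with probability
`1 - exp(-rate * dt)` computed from the pre-step state, with `dt = 1` by
default. The rate-to-probability map is a choice (the continuous-time rates
do not uniquely determine a synchronous scheme); this one keeps
probabilities valid for any rate and matches the rates to first order in
`dt`. `dt` is exposed, and `dt` well below 1 approaches the continuous-time
process — a point that matters below.

Short-range facilitation plus displaced competition produces banding:
vegetation stripes perpendicular to `theta`. A band suppresses recruitment a
distance `r` downstream, so the stationary spacing is close to `2r` with the
suppressed zone mid-gap — a regularity the prior construction exploits. Both
kernels are truncated at `ceil(r + 4*sigma)` lattice units and normalised to
unit sum over the truncated support, so `[k * S]` is a density in [0, 1] and
`lam`, `c` are interpretable as maximal rates; the tail mass discarded at 4
standard deviations is below 1e-4.

```{r, eval = FALSE}
library(bandinfer)
gen <- model_params(sigma1 = 0.6, sigma2 = 2, c = 1, r = 10, theta = 1.5)
snap <- simulate_pca(gen, n_rows = 100, n_cols = 100, n_steps = 1000,
                     init_occupancy = 0.1, seed = 1)
plot(snap)
```

## The synthetic likelihood

The full transition likelihood of a snapshot is intractable, but the
correlation structure of a stationary pattern constrains the rates. For
pair types XY in {00, 01, 11} and Euclidean distances `d = 1, ..., k`
(default `k = 20`, integer-rounded distance classes), the package computes
`xi_XY(d)`: the expected instantaneous rate of change of the ordered pair
count `N_XY(d)`, summing rate times pair-count change over all single-site
events (first-order transitions only). A death at an occupied site `s`
converts 11 pairs into 01 and 01 into 00 in proportion to the occupied and
empty neighbours of `s` at each distance; a birth does the reverse. If the
observed pattern is statistically stationary under the proposed parameters,
every `xi_XY(d)` is zero in expectation, so the vector of statistics
measures how far a parameter vector is from explaining the snapshot.

Each statistic is treated as an independent zero-mean normal with variance
`tau^2 * N(d)^2` — the fluctuation scale of a raw pair-count rate grows
linearly with the number of pairs — giving the log-likelihood
`-sum_i [log(2*pi*tau_i^2)/2 + xi_i^2/(2*tau_i^2)]`. `tau^2` defaults to
1e-6 for a 100 x 100 lattice; `calibrate_tau()` re-derives it from
simulation runs (record `xi` at stationarity, return the median over
statistics of `Var(xi_i)/N(d)^2`) and on 100 x 100 banding runs lands at a
few times 1e-6 under this package's ordered-pair counting. Two conventions
are worth stating because they rescale constants but not conclusions:
pairs are counted ordered (each unordered pair from both endpoints — this
is what makes per-site sums and global counts consistent without 1/2
factors), and `xi` is the derivative of those ordered counts, which is
exactly what the brute-force oracle below measures. `Var(xi)/N^2` is
invariant to the ordered/unordered choice.

Correctness of the statistics rests on an independent oracle:
`brute_force_expected_change()` flips every site in turn, recounts all pair
counts of the flipped lattice from scratch by naive modular indexing, and
accumulates rate times count change. The fast path (per-site neighbour-count
fields plus two convolutions) must agree with it to relative 1e-10; this is
the package's core correctness test, run on over a hundred random small
lattices.

The per-site neighbour-count fields of the data lattice are precomputed
once per snapshot, so each likelihood evaluation costs two FFT convolutions
plus a few `k`-column weighted sums, and a component-wise MCMC update
recomputes at most one kernel. This is what makes 1e5-1e6 iterations
feasible on one CPU.

## Boundary policy

Simulated lattices are periodic. Observed snapshots are bounded: sites
beyond the image edge are unknown, so pair counts and expected-change
statistics sum only over focal sites at least `margin` from every edge
(`margin >= k` for pair counts; `margin >= k + kernel half-width` for the
statistics, so that rates are fully observed too). Neighbours of focal
sites may lie in the margin. On a periodic lattice the margin is zero.

## Priors measured from the band geometry

Weakly informative priors anchor the parameters to the biologically
realistic regime in which competition acts at about the nearest band:

* `r ~ Exponential(mean = wavelength)`, the band-to-band spacing;
* `sigma1^2 ~ Gamma(mean = band width, variance = 0.1 * L)` and
  `sigma2^2 ~ Gamma(mean = gap width, variance = 0.1 * L)`, `L` the lattice
  side (variance in squared lattice units — the natural reading that keeps
  the priors wide);
* `c ~ Exponential(mean = 1)`;
* `theta ~ Uniform[0, 2*pi)` by default. An interval of `[0, pi]` (the
  stated alternative, identifying only the competition axis) is
  configurable, but the full circle is the default because the posterior
  for a banded snapshot genuinely carries two mirror modes at `theta` and
  `theta + pi`, and the wider prior lets both be seen.

`estimate_band_metrics()` measures the geometry: the centred 2-D
autocorrelation is profiled along a fan of directions, the direction with
the strongest secondary maximum is the band normal and the peak lag the
wavelength; band and gap widths are mean run lengths along the normal after
a short Gaussian smoothing (sigma 2) and re-thresholding at the mean
occupancy, because bands are porous and raw 0/1 runs would measure the
pores. Patternless input (secondary peak below 0.1) falls back to run-length
estimates and sets a low-confidence flag.

## Posterior sampling

`fit_snapshot()` runs component-wise Gaussian random-walk
Metropolis–Hastings on `(sigma1^2, sigma2^2, c, r, theta)` — the variance
coordinates, so the gamma priors apply directly. Proposal scales adapt
during burn-in by a factor 1.1 per 100-iteration block toward 25%
per-parameter acceptance, within a +/-0.05 deadband (block rates have a
standard deviation of about 4 points, and without the deadband converged
scales random-walk and freeze at an arbitrary phase); scales are frozen
after burn-in and no thinning is applied. Negative proposals die by prior
support; proposals whose kernel would not fit the periodic lattice are
rejected the same way (an implicit truncation of the prior at physically
meaningless kernel sizes).

Two further moves address the shape of this particular posterior:

* **Mirror jumps.** The likelihood is nearly symmetric under
  `theta -> theta + pi`, so the posterior is bimodal with well-separated
  modes that a random walk cannot hop between. Once per sweep the sampler
  proposes the half-turn (a symmetric involution on the full circle, hence
  a valid plain-MH move). The mirror modes carry genuinely unequal mass on
  any finite snapshot, so the bimodality diagnostic in
  `summary()`/`circular_modes()` flags a secondary peak at 20% of the main
  peak's height rather than demanding equal heights.
* **Multi-start initialisation by successive halving.** Besides the broad
  data-consistent basin, the synthetic likelihood has narrow spurious
  optima — most prominently a "wavelength mode" near `r ~ 2 r_true`, where
  the displaced competition lands on the next band over. Pilot chains
  started from independent prior draws are raced in rounds (10 chains for
  600 sweeps, the best 4 for 1200 more, the best 2 for 3000 more), and the
  surviving state seeds the main burn-in. Ranking only after the survivors
  have descended well into their basins is essential: the spurious optima
  are only ~10 log-units below the true basin's floor.

Defaults follow the reference procedure (1e4 burn-in, 1e6 retained
sweeps); the validation experiments in the tests use 5e3 + 5e4, which takes
a few minutes on one CPU and is enough for stable marginal modes and
intervals at this lattice size.

## What the synthetic-data validation shows — and what it does not

The generator is first-class, tested code, and its defaults are the
benchmark conditions: 100 x 100 periodic lattice, 10% random initial
occupancy, 1000 synchronous steps at
`sigma1 = 0.6, sigma2 = 2, c = 1, r = 10, theta = 1.5` — a strong-banding
regime. On such snapshots the fit recovers the competition offset and
direction cleanly: the `r` marginal modes within about 5-10% of 10 across
seeds, and the `theta` marginal carries modes near 1.45 and 1.45 + pi.
The mass of the mirror mode varies strongly between snapshot realisations —
on some lattices the mirror basin sits several log-units below the main one
and the marginal is effectively unimodal, on others it holds ~10% of the
mass — and the location of the ridge itself scatters by a few tenths of a
radian around the generating value. The acceptance adaptation lands each
parameter in the 0.15-0.35 band.

The credible intervals for `sigma1^2`, `sigma2^2` and `c` at
`tau^2 = 1e-6`, however, can exclude the generating values. This is a real,
diagnosable property of the estimator under these study conditions, not a
sampling failure: the expected-change statistics assume the continuous-time
rate balance, while the data come from the synchronous `dt = 1` update
whose stationary state deviates from that balance at second order in the
per-step flip probabilities (which reach ~0.6 here). Re-generating the
benchmark at `dt = 0.25` (four times finer, same physical duration) removes
the `sigma2^2` discrepancy entirely (posterior 4.14 +/- 0.13 against a
truth of 4) and most of the `c` discrepancy, confirming the mechanism. The
remaining `sigma1^2` shift traces to the prior: with a measured band width
near 10, the gamma prior (shape ~9) has a strong upward gradient at the
true 0.36, and the likelihood for `sigma1^2` is not sharp enough to
override it. Widening `tau^2` to its calibrated value (a few times 1e-6)
widens all intervals accordingly.

The practical reading for real data: modes and intervals for `r` and
`theta` are trustworthy where banding is strong; `c` and the kernel widths
are informative but their intervals inherit a discretisation-scale
systematic when the underlying dynamics are fast relative to the census
interval. None of this validation speaks to misclassified imagery,
landscape heterogeneity, or non-Gaussian kernels — the model assumes a
homogeneous landscape and isotropic Gaussian kernels throughout.

## Numerical choices and degenerate inputs

* Distance classes: round-half-even on the Euclidean distance, classes
  1..k; class 1 therefore has 8 vectors (the diagonals round to 1).
* Kernel underflow: for sigma below ~1e-2 with a non-integer mean, every
  truncated-support weight can underflow; the kernel then degenerates to a
  point mass at the integer displacement nearest its mean (the correct
  sigma -> 0 limit).
* FFT convolution clamps round-off: values are clipped to [0, 1], exact
  bounds for unit-sum kernels on a binary lattice.
* Mode estimates are midpoints of 50-bin histograms — reproducible without
  density-estimation tuning; equal-tailed 2.5%-97.5% quantile intervals.
* Calibration discards the first 50% of each run as transient (relaxation
  is much faster; the cutoff is deliberately generous), discards extinct
  runs, and errors if all runs go extinct or all statistics are constant.
* `normality_check()` standardises each series with its own mean and
  standard deviation before the KS test, which makes the test
  conservative; constant series are flagged, not tested.
* An all-zero or all-one lattice has no band geometry and
  `estimate_band_metrics()` refuses it; frozen dynamics (`lam = 0, c = 0`)
  leave any lattice unchanged.

## Problem sizes used by the shipped experiments

The test suite runs the oracle comparison on lattices up to 10 x 10
(k = 3), property checks on 12-40 squares, and one full benchmark cycle:
a 1000-step 100 x 100 simulation with statistics recorded every other step,
a tau^2 calibration from three 400-step 100 x 100 runs, and a 5e3 + 5e4
MH fit. The acceptance script repeats the simulate-and-fit cycle from a
user seed. These sizes give stable results in minutes on a single CPU;
larger snapshots mainly tighten the likelihood further.

## Known limitations

* Single-snapshot inference conditions on statistical stationarity; a
  transient pattern (e.g. shortly after a disturbance) violates the core
  assumption and will bias all parameters.
* Statistics are assumed independent across pair types and distances; no
  covariance is estimated.
* The likelihood sharpness constant `tau^2` is global; its lattice-size
  dependence is left to explicit re-calibration.
* Weak or absent banding leaves `r` and `theta` close to their priors —
  the method resolves parameters only as far as the pattern constrains
  them.
* Anisotropic correlation functions, triplet correlations, non-Gaussian or
  asymmetric kernels, and spatially varying parameters are out of scope.
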