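#' Model parameters of the birth-death lattice model
#'
#' The model has six parameters: birth rate `lam` (fixed to 1 in fitting,
#' since a single snapshot carries no absolute time scale), the standard
#' deviations `sigma1` (growth kernel) and `sigma2` (competition kernel),
#' competition strength `c`, and the competition-kernel offset given by
#' displacement `r` and angle `theta` (radians from +x toward +y, wrapped into
#' \[0, 2*pi)). Banding emerges when competition is displaced by roughly one
#' band wavelength (`r` large compared with `sigma1`); bands form
#' perpendicular to `theta`.
#'
#' @param lam nonnegative birth rate; default 1 (zero freezes births).
#' @param sigma1 positive growth-kernel standard deviation, lattice units.
#' @param sigma2 positive competition-kernel standard deviation.
#' @param c nonnegative competition strength (death-rate multiplier).
#' @param r nonnegative competition offset displacement, lattice units.
#' @param theta offset angle in radians.
#' @return an object of class `model_params` (named list).
#' @examples
#' model_params(sigma1 = 0.6, sigma2 = 2, c = 1, r = 10, theta = 1.5)
#' @export
model_params <- function(sigma1, sigma2, c, r, theta, lam = 1) {
  if (!(sigma1 > 0) || !(sigma2 > 0))
    stop("`sigma1` and `sigma2` must be positive")
  if (lam < 0) stop("`lam` must be nonnegative")
  if (c < 0 || r < 0) stop("`c` and `r` must be nonnegative")
  theta <- theta %% (2 * pi)
  structure(list(lam = lam, sigma1 = sigma1, sigma2 = sigma2, c = c,
                 r = r, theta = theta), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "model_params: lam=%g sigma1=%g sigma2=%g c=%g r=%g theta=%g\n",
    x$lam, x$sigma1, x$sigma2, x$c, x$r, x$theta))
  invisible(x)
}

model_kernels <- function(params, truncation_mult = 4) {
  list(k1 = build_kernel(params$sigma1, 0, 0, truncation_mult),
       k2 = build_kernel(params$sigma2, params$r, params$theta,
                         truncation_mult))
}

#' Birth and death rate fields
#'
#' Computes the per-site event rates of the model: empty sites gain occupancy
#' at rate `lam * [k1 * S]` (facilitation by nearby occupied sites) and
#' occupied sites die at rate `c * [k2 * S]` (competition from the offset
#' neighbourhood). Rates are masked so that `birth` is nonzero only at empty
#' sites and `death` only at occupied sites.
#'
#' For bounded snapshots the rates within a kernel half-width of the edge are
#' computed with zero padding and are therefore unreliable; the fitting
#' machinery only consumes interior sites.
#'
#' @param lattice a [binary_lattice()].
#' @param params a [model_params()].
#' @param truncation_mult kernel truncation, see [build_kernel()].
#' @return list of numeric matrices `birth` and `death`.
#' @export
compute_rates <- function(lattice, params, truncation_mult = 4) {
  ks <- model_kernels(params, truncation_mult)
  S <- as_grid(lattice)
  birth <- params$lam * convolve_lattice(lattice, ks$k1) * (1 - S)
  death <- params$c * convolve_lattice(lattice, ks$k2) * S
  list(birth = birth, death = death)
}

#' One synchronous update of the lattice
#'
#' Every site flips independently with probability `1 - exp(-rate * dt)`,
#' where `rate` is its birth rate (if empty) or death rate (if occupied), all
#' rates being computed from the pre-step state. This maps the continuous-time
#' event rates onto a synchronous update while keeping probabilities in
#' \[0, 1\] for any rate; `dt` below 1 approaches the continuous-time process.
#'
#' Uses the current R random number stream; seed control belongs to
#' [simulate_pca()].
#'
#' @param lattice a periodic [binary_lattice()].
#' @param params a [model_params()].
#' @param dt positive time step; default 1.
#' @return the updated [binary_lattice()].
#' @export
step_lattice <- function(lattice, params, dt = 1) {
  if (!(dt > 0)) stop("`dt` must be positive")
  if (!is_periodic(lattice)) stop("simulation requires a periodic lattice")
  rates <- compute_rates(lattice, params)
  step_lattice_impl(lattice, rates$birth + rates$death, dt)
}

step_lattice_impl <- function(lattice, rate, dt) {
  S <- as_grid(lattice)
  p_flip <- 1 - exp(-rate * dt)
  flips <- matrix(stats::runif(length(S)) < p_flip, nrow(S), ncol(S))
  binary_lattice((S + flips) %% 2L, boundary = "periodic")
}

#' Forward-simulate the probabilistic cellular automaton
#'
#' Runs the synchronous birth-death dynamics from a random initial condition
#' (or a supplied lattice) for `n_steps` steps. The standard pattern-forming
#' protocol is a 100 x 100 periodic lattice initialised at 10% occupancy and
#' run for 1000 steps, by which point the population size and pair-wise
#' correlations have reached statistical stationarity.
#'
#' `record = "stats"` additionally records, at every `record_stride`-th step,
#' the occupied fraction and the pair-wise correlations `P00/P01/P11(d)`;
#' with `record_xi = TRUE` also the expected pair-change statistics
#' `xi_XY(d)` evaluated at the simulation parameters (used for likelihood
#' variance calibration and stationarity diagnostics). `record = "trajectory"`
#' keeps the lattice at every recorded step.
#'
#' @param params a [model_params()].
#' @param n_rows,n_cols lattice dimensions; default 100 x 100.
#' @param n_steps number of synchronous steps; default 1000.
#' @param init_occupancy initial random occupancy; default 0.1.
#' @param dt time step; default 1.
#' @param seed optional integer seed (reproducible runs).
#' @param init optional periodic [binary_lattice()] used instead of a random
#'   initial condition.
#' @param record `"final"`, `"stats"` or `"trajectory"`.
#' @param classes distance classes for `record = "stats"`; default k = 20.
#' @param record_stride record every this-many steps; default 1.
#' @param record_xi also record expected pair-change statistics (stats mode).
#' @return `record = "final"`: the final [binary_lattice()]. Otherwise an
#'   object of class `pca_simulation`: list with `final`, `stats` (data frame
#'   with `step`, `occupied_fraction`, `P00_1`, ... columns), `xi` (matrix of
#'   xi statistics by recorded step, or NULL), `N_d` (total ordered pairs per
#'   distance), `trajectory` (list of lattices, or NULL), `params`, `dt`,
#'   `seed`.
#' @export
simulate_pca <- function(params, n_rows = 100, n_cols = 100, n_steps = 1000,
                         init_occupancy = 0.1, dt = 1, seed = NULL,
                         init = NULL, record = c("final", "stats", "trajectory"),
                         classes = NULL, record_stride = 1L,
                         record_xi = FALSE) {
  record <- match.arg(record)
  if (n_steps < 0) stop("`n_steps` must be nonnegative")
  runner <- function() {
    lat <- if (is.null(init)) {
      random_lattice(n_rows, n_cols, init_occupancy)
    } else {
      if (!is_periodic(init)) stop("`init` lattice must be periodic")
      init
    }
    simulate_impl(lat, params, n_steps, dt, record, classes, record_stride,
                  record_xi)
  }
  out <- if (is.null(seed)) runner() else with_seed(seed, runner())
  if (record == "final") return(out$final)
  out$seed <- seed
  out
}

simulate_impl <- function(lat, params, n_steps, dt, record, classes,
                          record_stride, record_xi) {
  n_r <- nrow(lat); n_c <- ncol(lat); n <- n_r * n_c
  want_stats <- record %in% c("stats", "trajectory")
  if (want_stats && is.null(classes)) classes <- build_distance_classes(20)
  ks <- model_kernels(params)
  K1 <- kernel_fft(ks$k1, n_r, n_c)
  K2 <- kernel_fft(ks$k2, n_r, n_c)
  cfs <- if (want_stats) class_kernel_ffts(classes, n_r, n_c)
  sizes <- if (want_stats) classes$sizes
  rec_steps <- if (want_stats) seq(0L, n_steps, by = record_stride)
  stats_rows <- list(); xi_rows <- list(); traj <- list()
  S <- as_grid(lat)
  snapshot <- function(step_no, F) {
    nb <- neighbor_fields_fft(F, cfs, n_r, n_c)
    occ_frac <- mean(S)
    N11 <- vapply(seq_along(nb), function(d) sum(nb[[d]] * S), 0)
    Ntot <- n * sizes
    N01 <- vapply(seq_along(nb), function(d)
      sum(nb[[d]] * (1 - S)) + sum((sizes[d] - nb[[d]]) * S), 0)
    N00 <- Ntot - N01 - N11
    row <- c(step = step_no, occupied_fraction = occ_frac,
             stats::setNames(N00 / Ntot, paste0("P00_", seq_along(nb))),
             stats::setNames(N01 / Ntot, paste0("P01_", seq_along(nb))),
             stats::setNames(N11 / Ntot, paste0("P11_", seq_along(nb))))
    stats_rows[[length(stats_rows) + 1L]] <<- row
    if (record_xi) {
      b1 <- conv_from_fft(F, K1); b2 <- conv_from_fft(F, K2)
      r1 <- params$lam * b1 * (1 - S)   # birth rates at empty sites
      r0 <- params$c * b2 * S           # death rates at occupied sites
      xi <- unlist(lapply(seq_along(nb), function(d) {
        n1 <- nb[[d]]; n0 <- sizes[d] - n1
        xi00 <- 2 * (sum(r0 * n0) - sum(r1 * n0))
        xi11 <- 2 * (sum(r1 * n1) - sum(r0 * n1))
        c(xi00, -(xi00 + xi11), xi11)
      }))
      names(xi) <- as.vector(t(outer(seq_along(nb), c("00", "01", "11"),
                                     function(d, p) paste0("xi", p, "_", d))))
      xi_rows[[length(xi_rows) + 1L]] <<- xi
    }
    if (record == "trajectory")
      traj[[length(traj) + 1L]] <<- binary_lattice(S, "periodic")
  }
  for (step_no in seq_len(n_steps + 1L) - 1L) {
    F <- if (want_stats || step_no < n_steps) stats::fft(S)
    if (want_stats && step_no %in% rec_steps) snapshot(step_no, F)
    if (step_no < n_steps) {
      b1 <- conv_from_fft(F, K1); b2 <- conv_from_fft(F, K2)
      rate <- params$lam * b1 * (1 - S) + params$c * b2 * S
      p_flip <- 1 - exp(-rate * dt)
      flips <- stats::runif(n) < p_flip
      S <- matrix((as.vector(S) + flips) %% 2L, n_r, n_c)
    }
  }
  final <- binary_lattice(S, "periodic")
  if (!want_stats) return(list(final = final))
  structure(list(
    final = final,
    stats = as.data.frame(do.call(rbind, stats_rows)),
    xi = if (record_xi) do.call(rbind, xi_rows),
    N_d = n * sizes,
    trajectory = if (record == "trajectory") traj,
    params = params, dt = dt, classes_k = classes$k
  ), class = "pca_simulation")
}

#' @export
print.pca_simulation <- function(x, ...) {
  cat(sprintf(
    "pca_simulation: %d x %d lattice, %d recorded steps, final occupancy %.3f\n",
    nrow(x$final), ncol(x$final), nrow(x$stats), occupancy(x$final)))
  invisible(x)
}
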