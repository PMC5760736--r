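#' Measure band geometry from a snapshot
#'
#' Extracts the geometric quantities used to build the empirical priors: the
#' dominant band-normal direction, the band-to-band wavelength, and the mean
#' widths of occupied bands and of the gaps between them.
#'
#' The centred two-dimensional autocorrelation of the lattice is profiled
#' along a fan of directions; the direction whose radial profile has the
#' strongest secondary maximum is taken as the band normal, and the lag of
#' that maximum as the wavelength. Band and gap widths are mean run lengths
#' of 1s and 0s sampled along lines in the band-normal direction. On
#' patternless input (no secondary autocorrelation peak) the wavelength falls
#' back to band width + gap width and the estimate is flagged low-confidence.
#'
#' @param lattice a [binary_lattice()] containing both states.
#' @param max_lag maximum autocorrelation lag profiled; default
#'   `floor(min(dim)/2) - 1`, capped at 30.
#' @param n_angles number of directions in `[0, pi)`; default 36.
#' @param min_peak minimum secondary-peak height (correlation units) below
#'   which the input is treated as patternless; default 0.1.
#' @return an object of class `band_metrics`: list with `band_width`,
#'   `gap_width`, `wavelength`, `orientation` (radians), `peak_corr` and
#'   `low_confidence`.
#' @export
estimate_band_metrics <- function(lattice, max_lag = NULL, n_angles = 36L,
                                  min_peak = 0.1) {
  S <- as_grid(lattice)
  p <- mean(S)
  if (p == 0 || p == 1)
    stop("lattice must contain both occupied and empty sites")
  n_r <- nrow(S); n_c <- ncol(S)
  if (is.null(max_lag)) max_lag <- min(30L, min(n_r, n_c) %/% 2L - 1L)
  # centred, normalised circular autocorrelation (periodic approximation is
  # adequate for prior construction on bounded snapshots too)
  Sc <- S - p
  F <- stats::fft(Sc)
  ac <- Re(stats::fft(F * Conj(F), inverse = TRUE)) / length(S)
  ac <- ac / ac[1, 1]
  angles <- seq(0, pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  best <- list(height = -Inf, angle = NA_real_, lag = NA_real_)
  for (a in angles) {
    prof <- vapply(seq_len(max_lag), function(l)
      ac_interp(ac, l * cos(a), l * sin(a)), 0)
    pk <- secondary_peak(prof)
    if (!is.null(pk) && pk$height > best$height)
      best <- list(height = pk$height, angle = a, lag = pk$lag)
  }
  low_conf <- !is.finite(best$height) || best$height < min_peak
  orientation <- if (low_conf) 0 else best$angle
  runs <- directional_run_lengths(S, orientation)
  band_width <- runs$mean_run1
  gap_width <- runs$mean_run0
  wavelength <- if (low_conf) band_width + gap_width else best$lag
  structure(list(band_width = band_width, gap_width = gap_width,
                 wavelength = wavelength, orientation = orientation,
                 peak_corr = if (low_conf) NA_real_ else best$height,
                 low_confidence = low_conf),
            class = "band_metrics")
}

#' @export
print.band_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "band_metrics: wavelength %.2f, band %.2f, gap %.2f, ",
    "orientation %.2f rad%s\n"),
    x$wavelength, x$band_width, x$gap_width, x$orientation,
    if (x$low_confidence) " (low confidence)" else ""))
  invisible(x)
}

# Bilinear interpolation of the wrapped autocorrelation surface at real lag
# (dx, dy); ac has lag (0,0) at [1,1] with wrap-around.
ac_interp <- function(ac, dx, dy) {
  n_r <- nrow(ac); n_c <- ncol(ac)
  y0 <- floor(dy); x0 <- floor(dx)
  fy <- dy - y0; fx <- dx - x0
  at <- function(yy, xx) ac[(yy %% n_r) + 1L, (xx %% n_c) + 1L]
  (1 - fy) * (1 - fx) * at(y0, x0) + (1 - fy) * fx * at(y0, x0 + 1) +
    fy * (1 - fx) * at(y0 + 1, x0) + fy * fx * at(y0 + 1, x0 + 1)
}

# First local maximum of `prof` occurring after the first local minimum:
# the band-to-band echo in the autocorrelation. NULL if none.
secondary_peak <- function(prof) {
  n <- length(prof)
  if (n < 4L) return(NULL)
  dmin <- NA_integer_
  for (i in 2:(n - 1L)) {
    if (is.na(dmin) && prof[i] <= prof[i - 1L] && prof[i] <= prof[i + 1L]) {
      dmin <- i
    } else if (!is.na(dmin) && prof[i] >= prof[i - 1L] && prof[i] > prof[i + 1L]) {
      return(list(lag = i, height = prof[i] - prof[dmin]))
    }
  }
  NULL
}

# Mean run lengths of bands (1s) and gaps (0s) along lines in direction
# `angle`, sampled by nearest site with periodic wrap; runs touching a line
# end are dropped. The raw lattice is first smoothed with a short Gaussian
# and re-thresholded at the mean occupancy, because bands are porous (sites
# inside a band are occupied with probability well below 1) and raw 0/1 run
# lengths would measure the pores, not the bands.
directional_run_lengths <- function(S, angle, n_lines = NULL,
                                    smooth_sigma = 2) {
  n_r <- nrow(S); n_c <- ncol(S)
  if (smooth_sigma > 0 && min(n_r, n_c) > 8 * smooth_sigma + 2) {
    lat <- binary_lattice(S, "periodic")
    dens <- convolve_lattice(lat, build_kernel(smooth_sigma))
    S <- matrix(as.integer(dens >= mean(S)), n_r, n_c)
  }
  len <- min(n_r, n_c)
  if (is.null(n_lines)) n_lines <- len
  starts_r <- round(seq(1, n_r, length.out = n_lines))
  starts_c <- round(seq(1, n_c, length.out = n_lines))
  run1 <- c(); run0 <- c()
  for (s in seq_len(n_lines)) {
    t <- seq_len(len) - 1L
    rr <- ((starts_r[s] - 1L + round(t * sin(angle))) %% n_r) + 1L
    cc <- ((starts_c[s] - 1L + round(t * cos(angle))) %% n_c) + 1L
    seq_states <- S[cbind(rr, cc)]
    rl <- rle(seq_states)
    if (length(rl$lengths) > 2L) {
      keep <- 2:(length(rl$lengths) - 1L)
      run1 <- c(run1, rl$lengths[keep][rl$values[keep] == 1L])
      run0 <- c(run0, rl$lengths[keep][rl$values[keep] == 0L])
    }
  }
  list(mean_run1 = if (length(run1)) mean(run1) else 1,
       mean_run0 = if (length(run0)) mean(run0) else 1)
}

#' Empirical prior specification
#'
#' Builds the weakly informative priors used in fitting, anchored to the
#' measured band geometry so that the parameters are constrained to the
#' biologically realistic regime (competition acting at about the
#' nearest-neighbour band): exponential prior on the competition offset `r`
#' with mean equal to the band wavelength; gamma priors on the kernel
#' variances `sigma1^2` and `sigma2^2` with means equal to the band width and
#' gap width and variance `0.1 * L` (one tenth of the lattice side, in
#' squared lattice units); exponential prior with mean 1 on the competition
#' strength `c`; uniform prior on the offset angle `theta`.
#'
#' @param metrics a [estimate_band_metrics()] result.
#' @param L lattice side (maximum of the two dimensions).
#' @param theta_interval support of the uniform angle prior; default
#'   `c(0, 2*pi)`. The interval `c(0, pi)` identifies the axis only and
#'   suppresses the mirror mode at `theta + pi`.
#' @param overrides named list replacing any of `r_mean`, `sigma1_sq_mean`,
#'   `sigma2_sq_mean`, `gamma_var`, `c_mean`.
#' @return an object of class `prior_spec`.
#' @export
build_priors <- function(metrics, L, theta_interval = c(0, 2 * pi),
                         overrides = list()) {
  hp <- list(r_mean = metrics$wavelength,
             sigma1_sq_mean = metrics$band_width,
             sigma2_sq_mean = metrics$gap_width,
             gamma_var = 0.1 * L,
             c_mean = 1)
  for (nm in names(overrides)) {
    if (!nm %in% names(hp)) stop("unknown prior override: ", nm)
    if (!(overrides[[nm]] > 0)) stop("prior override `", nm, "` must be positive")
    hp[[nm]] <- overrides[[nm]]
  }
  gamma_par <- function(m, v) list(shape = m^2 / v, scale = v / m, mean = m, var = v)
  structure(list(
    r = list(dist = "exp", mean = hp$r_mean),
    sigma1_sq = c(list(dist = "gamma"), gamma_par(hp$sigma1_sq_mean, hp$gamma_var)),
    sigma2_sq = c(list(dist = "gamma"), gamma_par(hp$sigma2_sq_mean, hp$gamma_var)),
    c = list(dist = "exp", mean = hp$c_mean),
    theta = list(dist = "unif", min = theta_interval[1], max = theta_interval[2]),
    L = L), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "prior_spec: r ~ Exp(mean %.2f), sigma1_sq ~ Gamma(mean %.2f, var %.2f),\n",
    "  sigma2_sq ~ Gamma(mean %.2f, var %.2f), c ~ Exp(mean %.2f), ",
    "theta ~ U[%.2f, %.2f)\n"),
    x$r$mean, x$sigma1_sq$mean, x$sigma1_sq$var, x$sigma2_sq$mean,
    x$sigma2_sq$var, x$c$mean, x$theta$min, x$theta$max))
  invisible(x)
}

#' Log prior density
#'
#' Sum of the component log-densities of a [build_priors()] specification at
#' a parameter point in the sampling coordinates
#' `(sigma1_sq, sigma2_sq, c, r, theta)`; `-Inf` outside the support.
#'
#' @param x named numeric vector with elements `sigma1_sq`, `sigma2_sq`, `c`,
#'   `r`, `theta`, or a [model_params()] object.
#' @param prior a `prior_spec`.
#' @return scalar log density.
#' @export
log_prior <- function(x, prior) {
  if (inherits(x, "model_params"))
    x <- c(sigma1_sq = x$sigma1^2, sigma2_sq = x$sigma2^2, c = x$c,
           r = x$r, theta = x$theta)
  if (x[["sigma1_sq"]] <= 0 || x[["sigma2_sq"]] <= 0 ||
      x[["c"]] < 0 || x[["r"]] < 0)
    return(-Inf)
  if (x[["theta"]] < prior$theta$min || x[["theta"]] >= prior$theta$max)
    return(-Inf)
  stats::dgamma(x[["sigma1_sq"]], shape = prior$sigma1_sq$shape,
                scale = prior$sigma1_sq$scale, log = TRUE) +
    stats::dgamma(x[["sigma2_sq"]], shape = prior$sigma2_sq$shape,
                  scale = prior$sigma2_sq$scale, log = TRUE) +
    stats::dexp(x[["c"]], rate = 1 / prior$c$mean, log = TRUE) +
    stats::dexp(x[["r"]], rate = 1 / prior$r$mean, log = TRUE) -
    log(prior$theta$max - prior$theta$min)
}

#' @rdname log_prior
#' @param n number of draws.
#' @return `sample_prior`: an `n x 5` matrix of independent prior draws in
#'   the sampling coordinates.
#' @export
sample_prior <- function(prior, n = 1L) {
  cbind(sigma1_sq = stats::rgamma(n, shape = prior$sigma1_sq$shape,
                                  scale = prior$sigma1_sq$scale),
        sigma2_sq = stats::rgamma(n, shape = prior$sigma2_sq$shape,
                                  scale = prior$sigma2_sq$scale),
        c = stats::rexp(n, rate = 1 / prior$c$mean),
        r = stats::rexp(n, rate = 1 / prior$r$mean),
        theta = stats::runif(n, prior$theta$min, prior$theta$max))
}
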