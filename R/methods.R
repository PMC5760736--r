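#' @export
print.snapshot_fit <- function(x, ...) {
  cat(sprintf(
    "snapshot_fit: %d x %d %s lattice, k = %d, tau^2 = %g\n",
    nrow(x$lattice), ncol(x$lattice), attr(x$lattice, "boundary"), x$k,
    x$tau_sq))
  cat(sprintf("  %d burn-in + %d retained MH iterations (%.1f s)\n",
              x$n_burnin, x$n_samples, x$elapsed))
  cat(sprintf("  acceptance rates: %s\n",
              paste(sprintf("%s %.2f", names(x$acceptance_rate),
                            x$acceptance_rate), collapse = ", ")))
  cat("  posterior means:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' Point estimates from a fitted snapshot model
#'
#' @param object a [fit_snapshot()] result.
#' @param type `"mean"` (posterior mean, default) or `"mode"`
#'   (histogram-based marginal mode).
#' @param ... unused.
#' @return named vector `(sigma1_sq, sigma2_sq, c, r, theta)`; also includes
#'   the derived standard deviations `sigma1`, `sigma2`.
#' @export
coef.snapshot_fit <- function(object, type = c("mean", "mode"), ...) {
  type <- match.arg(type)
  d <- object$draws
  pars <- c("sigma1_sq", "sigma2_sq", "c", "r", "theta")
  est <- if (type == "mean") colMeans(d[, pars, drop = FALSE])
         else vapply(pars, function(p) hist_mode(d[, p]), 0)
  c(est, sigma1 = sqrt(unname(est["sigma1_sq"])),
    sigma2 = sqrt(unname(est["sigma2_sq"])))
}

#' Histogram-based marginal mode
#'
#' Midpoint of the tallest of `bins` equal-width histogram bins: a
#' reproducible mode estimate requiring no density-estimation tuning.
#'
#' @param x numeric draws.
#' @param bins number of bins; default 50.
#' @return scalar mode estimate.
#' @export
hist_mode <- function(x, bins = 50L) {
  if (length(unique(x)) == 1L) return(x[1L])
  h <- graphics::hist(x, breaks = seq(min(x), max(x), length.out = bins + 1L),
                      plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Modes of a circular marginal
#'
#' Bins draws of an angle into `bins` equal cells of the interval, finds
#' local maxima with circular neighbour comparison, and reports the peaks in
#' decreasing height. A marginal is flagged bimodal when a second peak,
#' separated from the main one by at least `min_sep` bins (circularly),
#' reaches at least `rel_height` of the main peak's height — the signature
#' of the direction/anti-direction ambiguity of the offset competition.
#'
#' @param theta numeric angle draws.
#' @param interval support, default `c(0, 2*pi)`.
#' @param bins number of bins; default 50.
#' @param min_sep minimum peak separation in bins; default 5.
#' @param rel_height fraction of the main peak a secondary peak must reach
#'   to flag bimodality; default 0.2. The mirror modes carry genuinely
#'   different posterior mass, so their histogram peaks can be far from
#'   equal height while both are real.
#' @return list with `modes` (angles, decreasing peak height), `heights`
#'   (bin counts) and `bimodal` flag.
#' @export
circular_modes <- function(theta, interval = c(0, 2 * pi), bins = 50L,
                           min_sep = 5L, rel_height = 0.2) {
  breaks <- seq(interval[1], interval[2], length.out = bins + 1L)
  cnt <- graphics::hist(theta, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE)$counts
  mids <- (breaks[-1L] + breaks[-(bins + 1L)]) / 2
  lft <- cnt[c(bins, seq_len(bins - 1L))]
  rgt <- cnt[c(seq.int(2L, bins), 1L)]
  is_peak <- cnt >= lft & cnt > rgt
  ord <- order(cnt, decreasing = TRUE)
  peaks <- ord[is_peak[ord]]
  if (length(peaks) == 0L) peaks <- ord[1L]
  sel <- peaks[1L]
  for (p in peaks[-1L]) {
    sep <- min(abs(p - sel) %% bins, (bins - abs(p - sel)) %% bins)
    if (min(sep) >= min_sep) sel <- c(sel, p)
  }
  bimodal <- length(sel) >= 2L && cnt[sel[2L]] >= rel_height * cnt[sel[1L]]
  list(modes = mids[sel], heights = cnt[sel], bimodal = bimodal)
}

#' Mirror-mode pair of a circular marginal
#'
#' The competition direction of a banded pattern is identified up to a
#' half-turn, so its posterior marginal carries a main mode and a mirror
#' partner near `theta + pi`. This helper locates the histogram peak in each
#' half of the circle relative to the main peak and returns both, with their
#' mass ratio — robust to small noise peaks near the main mode, unlike a
#' generic peak search.
#'
#' @param theta numeric angle draws on `[0, 2*pi)`.
#' @param bins number of histogram bins; default 50.
#' @return list with `modes` (main, mirror), `heights` (bin counts) and
#'   `mass_ratio` (fraction of draws in the mirror half).
#' @export
theta_mode_pair <- function(theta, bins = 50L) {
  breaks <- seq(0, 2 * pi, length.out = bins + 1L)
  cnt <- graphics::hist(theta %% (2 * pi), breaks = breaks, plot = FALSE,
                        include.lowest = TRUE)$counts
  mids <- (breaks[-1L] + breaks[-(bins + 1L)]) / 2
  main <- which.max(cnt)
  circ_dist <- pmin(abs(mids - mids[main]), 2 * pi - abs(mids - mids[main]))
  opp <- which(circ_dist > pi / 2)
  mirror <- opp[which.max(cnt[opp])]
  in_opp <- circ_dist[findInterval(theta %% (2 * pi), breaks,
                                   rightmost.closed = TRUE)] > pi / 2
  list(modes = c(main = mids[main], mirror = mids[mirror]),
       heights = c(cnt[main], cnt[mirror]),
       mass_ratio = mean(in_opp))
}

#' Summarise a fitted snapshot model
#'
#' Per-parameter histogram mode, posterior mean, standard deviation,
#' equal-tailed 95% credible interval and MH acceptance rate; the angle
#' `theta` is additionally summarised circularly, with a bimodality flag
#' (see [circular_modes()]). Rows for the kernel standard deviations
#' `sigma1`, `sigma2` are derived from the variance draws.
#'
#' @param object a [fit_snapshot()] result.
#' @param prob credible-interval mass; default 0.95.
#' @param ... unused.
#' @return an object of class `summary.snapshot_fit` with elements `table`
#'   (data frame), `theta_modes` and `theta_bimodal`.
#' @export
summary.snapshot_fit <- function(object, prob = 0.95, ...) {
  d <- object$draws
  a <- (1 - prob) / 2
  pars <- c("sigma1_sq", "sigma2_sq", "c", "r", "theta")
  mk <- function(x, nm, acc) data.frame(
    parameter = nm, mode = hist_mode(x), mean = mean(x), sd = stats::sd(x),
    ci_lower = unname(stats::quantile(x, a)),
    ci_upper = unname(stats::quantile(x, 1 - a)),
    acceptance = acc)
  tab <- do.call(rbind, lapply(pars, function(p)
    mk(d[, p], p, unname(object$acceptance_rate[p]))))
  tab <- rbind(tab,
               mk(sqrt(d[, "sigma1_sq"]), "sigma1", NA_real_),
               mk(sqrt(d[, "sigma2_sq"]), "sigma2", NA_real_))
  cm <- circular_modes(d[, "theta"],
                       interval = c(object$priors$theta$min,
                                    object$priors$theta$max))
  structure(list(table = tab, theta_modes = cm$modes,
                 theta_bimodal = cm$bimodal, prob = prob,
                 n_samples = object$n_samples),
            class = "summary.snapshot_fit")
}

#' @export
print.summary.snapshot_fit <- function(x, ...) {
  cat(sprintf("Posterior summary (%d draws, %.0f%% equal-tailed CI)\n",
              x$n_samples, 100 * x$prob))
  tab <- x$table
  tab[, -1L] <- round(tab[, -1L], 4)
  print(tab, row.names = FALSE)
  cat(sprintf("theta modes: %s%s\n",
              paste(round(x$theta_modes, 3), collapse = ", "),
              if (x$theta_bimodal) " (bimodal)" else ""))
  invisible(x)
}

#' Posterior-predictive simulation
#'
#' Draws parameter vectors from the chain, simulates each forward from
#' either a fresh random initial condition or the data lattice itself, and
#' compares the observed pair-wise correlations with the envelope of the
#' simulated ones.
#'
#' @param fit a [fit_snapshot()] result.
#' @param n_draws number of posterior draws to simulate; default 20.
#' @param n_steps forward steps per simulation; default 200.
#' @param init `"random"` (10% occupancy) or `"data"` (the fitted lattice).
#' @param seed optional integer seed.
#' @return an object of class `posterior_predictive`: list with `lattices`,
#'   `params` (the drawn parameter rows), and `comparison` — a data frame per
#'   distance `d` with the observed `P00/P01/P11` and the simulated envelope
#'   (min, max) of each.
#' @export
posterior_predict <- function(fit, n_draws = 20, n_steps = 200,
                              init = c("random", "data"), seed = NULL) {
  init <- match.arg(init)
  if (n_draws == 0)
    return(structure(list(lattices = list(), params = NULL,
                          comparison = NULL), class = "posterior_predictive"))
  run <- function() {
    idx <- sample.int(nrow(fit$draws), n_draws, replace = TRUE)
    sims <- lapply(idx, function(i) {
      p <- fit$draws[i, ]
      mp <- model_params(sigma1 = sqrt(p[["sigma1_sq"]]),
                         sigma2 = sqrt(p[["sigma2_sq"]]),
                         c = p[["c"]], r = p[["r"]], theta = p[["theta"]])
      init_lat <- if (init == "data")
        binary_lattice(as_grid(fit$lattice), "periodic") else NULL
      simulate_pca(mp, nrow(fit$lattice), ncol(fit$lattice), n_steps,
                   init = init_lat)
    })
    list(idx = idx, sims = sims)
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  classes <- build_distance_classes(fit$k)
  ptabs <- lapply(out$sims, function(l) pair_counts(l, classes))
  env <- function(col) {
    m <- vapply(ptabs, function(tt) tt[[col]], numeric(fit$k))
    list(lo = apply(m, 1L, min), hi = apply(m, 1L, max))
  }
  obs <- fit$pairs
  cmp <- data.frame(d = obs$d)
  for (col in c("P00", "P01", "P11")) {
    e <- env(col)
    cmp[[paste0(col, "_obs")]] <- obs[[col]]
    cmp[[paste0(col, "_lo")]] <- e$lo
    cmp[[paste0(col, "_hi")]] <- e$hi
  }
  structure(list(lattices = out$sims, params = fit$draws[out$idx, , drop = FALSE],
                 comparison = cmp), class = "posterior_predictive")
}

#' @export
print.posterior_predictive <- function(x, ...) {
  cat(sprintf("posterior_predictive: %d simulated lattices\n",
              length(x$lattices)))
  if (!is.null(x$comparison)) {
    cov11 <- mean(x$comparison$P11_obs >= x$comparison$P11_lo &
                  x$comparison$P11_obs <= x$comparison$P11_hi)
    cat(sprintf("  P11 envelope covers observed at %.0f%% of distances\n",
                100 * cov11))
  }
  invisible(x)
}

#' @export
#' @rdname posterior_predict
#' @param object,... method arguments (`...` passed to [posterior_predict()]).
predict.snapshot_fit <- function(object, ...) posterior_predict(object, ...)

#' Simulate lattices from the fitted posterior
#'
#' `simulate()` method: forward-simulates `nsim` lattices with parameters
#' drawn from the posterior chain (a thin wrapper over
#' [posterior_predict()]).
#'
#' @param object a [fit_snapshot()] result.
#' @param nsim number of lattices; default 1.
#' @param seed optional integer seed.
#' @param ... passed to [posterior_predict()] (`n_steps`, `init`).
#' @return list of [binary_lattice()] objects.
#' @export
simulate.snapshot_fit <- function(object, nsim = 1, seed = NULL, ...) {
  posterior_predict(object, n_draws = nsim, seed = seed, ...)$lattices
}

#' Plot a fitted snapshot model
#'
#' Shows the data lattice and the marginal posterior histograms of the five
#' parameters, with optional reference values (e.g. the truth for a
#' simulated benchmark).
#'
#' @param x a [fit_snapshot()] result.
#' @param truth optional named vector of reference parameter values in the
#'   sampling coordinates.
#' @param ... unused.
#' @export
plot.snapshot_fit <- function(x, truth = NULL, ...) {
  op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(t(as_grid(x$lattice))[, nrow(x$lattice):1],
                  col = c("white", "darkgreen"), axes = FALSE,
                  main = "snapshot", useRaster = TRUE)
  for (p in c("sigma1_sq", "sigma2_sq", "c", "r", "theta")) {
    graphics::hist(x$draws[, p], breaks = 50, main = p, xlab = p,
                   col = "grey80", border = NA)
    if (!is.null(truth) && p %in% names(truth))
      graphics::abline(v = truth[[p]], col = "blue", lwd = 2)
  }
  invisible(x)
}

#' @export
plot.binary_lattice <- function(x, ...) {
  graphics::image(t(as_grid(x))[, nrow(x):1], col = c("white", "darkgreen"),
                  axes = FALSE, useRaster = TRUE, ...)
  invisible(x)
}
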