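#' Synthetic-likelihood configuration
#'
#' @param tau_sq positive variance constant of the synthetic likelihood.
#'   The per-statistic variance is `tau_i^2 = tau_sq * N(d)^2`, reflecting
#'   that the fluctuation scale of the raw pair-change statistics grows
#'   linearly with the number of pairs. Default `1e-6`, appropriate for a
#'   100 x 100 lattice; [calibrate_tau()] re-derives it for other settings.
#' @param k maximum distance class; default 20.
#' @param margin focal-region margin (see [pair_counts()]); `NULL` picks the
#'   per-function default.
#' @return an object of class `likelihood_config`.
#' @export
likelihood_config <- function(tau_sq = 1e-6, k = 20, margin = NULL) {
  if (!(tau_sq > 0)) stop("`tau_sq` must be positive")
  structure(list(tau_sq = tau_sq, k = as.integer(k), margin = margin),
            class = "likelihood_config")
}

#' Synthetic log-likelihood of the expected-change statistics
#'
#' Treats each statistic `xi_i` (pair types 00, 01, 11 at distances
#' `1, ..., k`) as an independent zero-mean normal deviate with variance
#' `tau_i^2 = tau_sq * N(d_i)^2` and returns
#' `-sum_i [ log(2 pi tau_i^2)/2 + xi_i^2 / (2 tau_i^2) ]`. Larger deviations
#' from stationarity (larger `|xi_i|`) always decrease the value; the maximum
#' attainable, at `xi == 0`, is the negative normalising constant.
#'
#' @param stats an [expected_pair_change()] result.
#' @param pairs a [pair_counts()] table built from the same lattice with the
#'   same `k` and `margin`.
#' @param config a [likelihood_config()].
#' @return the scalar log-likelihood.
#' @export
log_likelihood <- function(stats, pairs, config = likelihood_config()) {
  if (attr(stats, "k") != attr(pairs, "k"))
    stop("`stats` and `pairs` were built with different k")
  if (attr(stats, "margin") != attr(pairs, "margin"))
    stop("`stats` and `pairs` were built with different margins")
  if (config$k != attr(stats, "k"))
    stop("`config$k` does not match the statistics")
  xi <- c(stats$xi00, stats$xi01, stats$xi11)
  tau_i_sq <- config$tau_sq * rep(pairs$N, 3L)^2
  -sum(0.5 * log(2 * pi * tau_i_sq) + xi^2 / (2 * tau_i_sq))
}

#' Calibrate the likelihood variance constant
#'
#' Runs forward simulations to statistical stationarity, records the
#' expected-change statistics over the post-relaxation portion of each run,
#' and returns `tau^2 = median_i Var(xi_i) / N(d_i)^2`, the single free
#' constant of the synthetic likelihood. The median over statistics (rather
#' than a mean) keeps a few broad-scale statistics from dominating.
#'
#' Runs that go extinct are discarded; if every run goes extinct, or the
#' dynamics are frozen (all statistics constant), calibration fails with an
#' error.
#'
#' @param param_list list of [model_params()] draws (one simulation per
#'   element), e.g. banding-regime parameters with jitter.
#' @param n_rows,n_cols lattice dimensions; default 100 x 100.
#' @param n_steps steps per run; default 400.
#' @param seed integer seed.
#' @param k maximum distance class; default 20.
#' @param relax_frac fraction of initial steps discarded as transient;
#'   default 0.5 (generous, relaxation is fast).
#' @param record_stride record every this-many steps; default 2.
#' @return the calibrated `tau_sq` (scalar), with attribute `per_statistic`
#'   carrying the full `Var(xi_i)/N(d_i)^2` vector.
#' @export
calibrate_tau <- function(param_list, n_rows = 100, n_cols = 100,
                          n_steps = 400, seed = NULL, k = 20,
                          relax_frac = 0.5, record_stride = 2L) {
  if (length(param_list) < 1L) stop("at least one parameter draw is required")
  classes <- build_distance_classes(k)
  ratios <- list()
  for (i in seq_along(param_list)) {
    sim <- simulate_pca(param_list[[i]], n_rows, n_cols, n_steps,
                        seed = if (is.null(seed)) NULL else seed + i,
                        record = "stats", classes = classes,
                        record_stride = record_stride, record_xi = TRUE)
    if (occupancy(sim$final) == 0) next  # extinct run
    keep <- sim$stats$step >= relax_frac * n_steps
    v <- apply(sim$xi[keep, , drop = FALSE], 2L, stats::var)
    ratios[[length(ratios) + 1L]] <- v / rep(sim$N_d, each = 3L)^2
  }
  if (length(ratios) == 0L)
    stop("calibration failed: every simulation run went extinct")
  per_stat <- colMeans(do.call(rbind, ratios))
  if (all(per_stat == 0))
    stop("calibration failed: dynamics are frozen (all statistics constant)")
  structure(stats::median(per_stat), per_statistic = per_stat)
}

#' Kolmogorov-Smirnov normality check of the statistic series
#'
#' Standardises each recorded statistic series and tests it against the
#' standard normal with a two-sided KS test. This backs the modelling
#' assumption that the stationary fluctuations of the expected-change
#' statistics are normal, which is what licenses the Gaussian synthetic
#' likelihood. Constant (degenerate) series are flagged rather than tested.
#'
#' @param xi_samples numeric matrix, rows = time points, columns =
#'   statistics (e.g. the `xi` element of a [simulate_pca()] stats run,
#'   post-relaxation rows only).
#' @param min_samples minimum rows required; default 30.
#' @return data frame with columns `statistic`, `ks_stat`, `p_value`,
#'   `degenerate`.
#' @export
normality_check <- function(xi_samples, min_samples = 30L) {
  xi_samples <- as.matrix(xi_samples)
  if (nrow(xi_samples) < min_samples)
    stop("need at least ", min_samples, " samples per statistic")
  res <- lapply(seq_len(ncol(xi_samples)), function(j) {
    x <- xi_samples[, j]
    if (stats::sd(x) == 0)
      return(data.frame(statistic = j, ks_stat = NA_real_,
                        p_value = NA_real_, degenerate = TRUE))
    z <- (x - mean(x)) / stats::sd(x)
    kt <- suppressWarnings(stats::ks.test(z, "pnorm"))
    data.frame(statistic = j, ks_stat = unname(kt$statistic),
               p_value = kt$p.value, degenerate = FALSE)
  })
  out <- do.call(rbind, res)
  nm <- colnames(xi_samples)
  if (!is.null(nm)) out$statistic <- nm
  out
}
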