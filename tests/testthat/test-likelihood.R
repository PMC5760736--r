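test_that("log-likelihood matches its closed form and is monotone in the
           deviations", {
  lat <- random_lattice(20, 20, 0.4, seed = 14)
  dc <- build_distance_classes(3)
  pairs <- pair_counts(lat, dc)
  params <- small_random_params(20)
  stats <- expected_pair_change(lat, params, dc)
  cfg <- likelihood_config(tau_sq = 2.5e-6, k = 3)

  tau_i_sq <- cfg$tau_sq * rep(pairs$N, 3)^2
  xi <- c(stats$xi00, stats$xi01, stats$xi11)
  by_hand <- -sum(0.5 * log(2 * pi * tau_i_sq) + xi^2 / (2 * tau_i_sq))
  expect_equal(log_likelihood(stats, pairs, cfg), by_hand, tolerance = 1e-12)

  # all-zero statistics attain the maximum: the negative normalising constant
  zero <- stats
  zero$xi00 <- zero$xi01 <- zero$xi11 <- rep(0, 3)
  expect_equal(log_likelihood(zero, pairs, cfg),
               -sum(0.5 * log(2 * pi * tau_i_sq)), tolerance = 1e-12)
  expect_gt(log_likelihood(zero, pairs, cfg),
            log_likelihood(stats, pairs, cfg))

  # one statistic, xi = 1, tau_i^2 = 1 -> -log(2*pi)/2
  one_pair <- pairs[1, , drop = FALSE]
  attr(one_pair, "k") <- 1L; attr(one_pair, "margin") <- 0L
  one_stat <- stats[1, , drop = FALSE]
  one_stat$xi00 <- 1; one_stat$xi01 <- 0; one_stat$xi11 <- 0
  attr(one_stat, "k") <- 1L; attr(one_stat, "margin") <- 0L
  cfg1 <- likelihood_config(tau_sq = 1 / one_pair$N^2, k = 1)
  expect_equal(log_likelihood(one_stat, one_pair, cfg1),
               -3 * 0.5 * log(2 * pi) - 0.5, tolerance = 1e-12)

  # increasing any |xi| strictly decreases the value
  worse <- stats
  worse$xi11[2] <- worse$xi11[2] + sign(worse$xi11[2] + 0.5) * 10
  expect_lt(log_likelihood(worse, pairs, cfg),
            log_likelihood(stats, pairs, cfg))

  # mismatched k errors out
  expect_error(log_likelihood(stats, pair_counts(lat, 4), cfg), "k")
})

test_that("log-likelihood is maximised over tau_sq at the mean squared
           normalised deviation", {
  lat <- random_lattice(15, 15, 0.5, seed = 21)
  dc <- build_distance_classes(3)
  pairs <- pair_counts(lat, dc)
  stats <- expected_pair_change(lat, small_random_params(15), dc)
  xi <- c(stats$xi00, stats$xi01, stats$xi11)
  opt <- mean(xi^2 / rep(pairs$N, 3)^2)
  ll <- function(t) log_likelihood(stats, pairs, likelihood_config(t, k = 3))
  expect_gt(ll(opt), ll(opt * 1.2))
  expect_gt(ll(opt), ll(opt / 1.2))
  num <- stats::optimize(ll, c(opt / 50, opt * 50), maximum = TRUE,
                         tol = opt * 1e-6)$maximum
  expect_equal(num, opt, tolerance = 1e-3)
})

test_that("tau calibration recovers an injected variance scale and rejects
           degenerate dynamics", {
  # frozen dynamics: all statistics constant -> calibration error
  frozen <- model_params(sigma1 = 0.5, sigma2 = 0.5, c = 0, r = 0,
                         theta = 0, lam = 0)
  expect_error(
    calibrate_tau(list(frozen), n_rows = 30, n_cols = 30, n_steps = 40,
                  seed = 1, k = 3),
    "frozen")

  # extinction-only draws -> calibration error
  doomed <- model_params(sigma1 = 0.6, sigma2 = 0.6, c = 8, r = 0, theta = 0)
  expect_error(
    calibrate_tau(list(doomed), n_rows = 30, n_cols = 30, n_steps = 120,
                  seed = 2, k = 3),
    "extinct")

  # a live run yields a positive finite constant with per-statistic detail
  tau <- calibrate_tau(list(benchmark_params()), n_rows = 40, n_cols = 40,
                       n_steps = 80, seed = 3, k = 5)
  expect_gt(as.numeric(tau), 0)
  expect_length(attr(tau, "per_statistic"), 15L)
})

test_that("KS normality check calibrates on true normals and flags
           degenerate series", {
  set.seed(77)
  x <- matrix(rnorm(200 * 40), 200, 40)
  res <- normality_check(x)
  expect_true(all(!res$degenerate))
  # the standardised KS test is conservative, so the rejection fraction
  # stays at or below the nominal level
  expect_lte(mean(res$p_value < 0.05), 0.2)

  const <- cbind(x[, 1], rep(2, 200))
  res2 <- normality_check(const)
  expect_identical(res2$degenerate, c(FALSE, TRUE))
  expect_true(is.na(res2$p_value[2]))
  expect_error(normality_check(x[1:10, ]), "at least")
})
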