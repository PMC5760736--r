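test_that("with a flat likelihood the chain recovers the prior marginals", {
  pr <- flat_priors()
  res <- run_fake_mh(function(p) 0, pr, n_burnin = 1000, n_samples = 20000,
                     seed = 5)
  d <- res$draws
  qs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  # quantile-quantile agreement with the analytic priors within MC error
  expect_equal(unname(quantile(d[, "r"], qs)),
               qexp(qs, 1 / pr$r$mean), tolerance = 0.12)
  expect_equal(unname(quantile(d[, "c"], qs)), qexp(qs, 1), tolerance = 0.12)
  expect_equal(unname(quantile(d[, "sigma1_sq"], qs)),
               qgamma(qs, shape = pr$sigma1_sq$shape,
                      scale = pr$sigma1_sq$scale), tolerance = 0.12)
  expect_equal(unname(quantile(d[, "theta"], qs)), qs * 2 * pi,
               tolerance = 0.12)
  # every draw respects the support
  expect_true(all(d[, c("sigma1_sq", "sigma2_sq", "c", "r")] > 0))
  expect_true(all(d[, "theta"] >= 0 & d[, "theta"] < 2 * pi))
  expect_true(all(is.finite(d[, "log_lik"]) & is.finite(d[, "log_prior"])))
})

test_that("a Gaussian likelihood in r is reproduced with the correct mean
           and sd (detailed balance sanity)", {
  pr <- flat_priors()
  res <- run_fake_mh(function(p) dnorm(p$r, mean = 6, sd = 0.7, log = TRUE),
                     pr, n_burnin = 2000, n_samples = 30000, seed = 8)
  d <- res$draws[, "r"]
  # posterior is prior x normal; with Exp(mean ~10) the tilt shifts the
  # normal mean by -sd^2/prior_mean, a small known amount
  shift <- 0.7^2 / pr$r$mean
  expect_equal(mean(d), 6 - shift, tolerance = 0.05)
  expect_equal(sd(d), 0.7, tolerance = 0.07)
  # acceptance adaptation lands in the working range for the constrained
  # parameter
  expect_gte(res$acceptance_rate[["r"]], 0.15)
  expect_lte(res$acceptance_rate[["r"]], 0.35)
})

test_that("chain summaries handle degenerate and known-distribution
           chains", {
  fit <- structure(list(
    draws = cbind(sigma1_sq = rep(1, 100), sigma2_sq = rep(2, 100),
                  c = rep(0.5, 100), r = rep(3, 100), theta = rep(1, 100),
                  log_lik = rep(0, 100), log_prior = rep(0, 100)),
    acceptance_rate = c(sigma1_sq = 0.2, sigma2_sq = 0.2, c = 0.2, r = 0.2,
                        theta = 0.2),
    priors = flat_priors(), n_samples = 100L),
    class = "snapshot_fit")
  s <- summary(fit)
  r_row <- s$table[s$table$parameter == "r", ]
  expect_equal(r_row$mode, 3)
  expect_equal(r_row$mean, 3)
  expect_equal(r_row$ci_lower, 3)
  expect_equal(r_row$ci_upper, 3)

  set.seed(3)
  z <- rnorm(50000)
  expect_equal(unname(quantile(z, c(0.025, 0.975))), c(-1.96, 1.96),
               tolerance = 0.03)
  # the mode estimate is quantised to bin midpoints (bin width ~0.36 here)
  expect_lt(abs(hist_mode(z, bins = 25)), 0.3)

  # circular bimodality detection on two mirror peaks
  th <- c(rnorm(6000, 1.5, 0.1), rnorm(4000, 1.5 + pi, 0.1)) %% (2 * pi)
  cm <- circular_modes(th)
  expect_true(cm$bimodal)
  expect_equal(sort(cm$modes[1:2]), c(1.5, 1.5 + pi), tolerance = 0.1)
  # unimodal input is not flagged
  expect_false(circular_modes(rnorm(5000, 2, 0.2))$bimodal)
})

test_that("posterior prediction returns empty output for zero draws and the
           data lattice for zero steps", {
  lat <- simulate_pca(benchmark_params(), 40, 40, 60, seed = 33)
  pr <- flat_priors()
  draws <- cbind(sigma1_sq = rep(0.36, 50), sigma2_sq = 4, c = 1, r = 10,
                 theta = 1.5, log_lik = 0, log_prior = 0)
  fit <- structure(list(
    draws = draws, lattice = lat,
    pairs = pair_counts(lat, build_distance_classes(5)),
    acceptance_rate = c(sigma1_sq = .2, sigma2_sq = .2, c = .2, r = .2,
                        theta = .2),
    priors = pr, k = 5L, n_samples = 50L), class = "snapshot_fit")

  expect_length(posterior_predict(fit, n_draws = 0)$lattices, 0L)

  pp <- posterior_predict(fit, n_draws = 2, n_steps = 0, init = "data",
                          seed = 4)
  expect_identical(unclass(pp$lattices[[1]])[seq_along(lat)],
                   unclass(lat)[seq_along(lat)])
  # zero-step prediction from the data reproduces the observed correlations
  expect_equal(pp$comparison$P11_lo, pp$comparison$P11_obs, tolerance = 1e-12)
  expect_equal(pp$comparison$P11_hi, pp$comparison$P11_obs, tolerance = 1e-12)
})
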