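test_that("rate fields are masked to the correct site states and bounded by
           the rate constants", {
  params <- benchmark_params()
  empty <- binary_lattice(matrix(0L, 50, 50), "periodic")
  r <- compute_rates(empty, params)
  expect_true(all(r$birth == 0) && all(r$death == 0))

  full <- binary_lattice(matrix(1L, 50, 50), "periodic")
  rf <- compute_rates(full, params)
  expect_true(all(rf$birth == 0))
  expect_equal(rf$death, matrix(1, 50, 50), tolerance = 1e-9)

  set.seed(2)
  lat <- random_lattice(40, 40, 0.3)
  S <- matrix(unclass(lat), 40, 40)
  rr <- compute_rates(lat, params)
  expect_true(all(rr$birth[S == 1] == 0))
  expect_true(all(rr$death[S == 0] == 0))
  expect_true(all(rr$birth >= 0 & rr$birth <= params$lam + 1e-12))
  expect_true(all(rr$death >= 0 & rr$death <= params$c + 1e-12))
})

test_that("synchronous step freezes with zero rates and matches the
           rate-to-probability map on a full lattice", {
  frozen <- model_params(sigma1 = 0.5, sigma2 = 0.5, c = 0, r = 0,
                         theta = 0, lam = 0)
  lat <- random_lattice(30, 30, 0.4, seed = 6)
  set.seed(1)
  out <- step_lattice(lat, frozen)
  expect_identical(unclass(out)[seq_along(out)], unclass(lat)[seq_along(lat)])
  expect_error(step_lattice(lat, frozen, dt = 0), "dt")

  # full lattice, c = 1, dt = 1: every site dies with prob 1 - exp(-1);
  # empirical fraction within 3 binomial sd
  full <- binary_lattice(matrix(1L, 100, 100), "periodic")
  set.seed(9)
  stepped <- step_lattice(full, benchmark_params())
  p <- 1 - exp(-1)
  frac_died <- 1 - occupancy(stepped)
  expect_lt(abs(frac_died - p), 3 * sqrt(p * (1 - p) / 1e4))

  # small dt: expected flip count approx (sum rates) * dt
  lat2 <- random_lattice(50, 50, 0.3, seed = 11)
  rates <- compute_rates(lat2, benchmark_params())
  total <- sum(rates$birth + rates$death)
  dt <- 0.01
  flips <- replicate(40, {
    s <- step_lattice(lat2, benchmark_params(), dt = dt)
    sum(unclass(s) != unclass(lat2))
  })
  expect_lt(abs(mean(flips) - total * dt) / (total * dt), 0.25)
})

test_that("simulation is reproducible, respects n_steps = 0 and reaches a
           banded stationary state", {
  params <- benchmark_params()
  a <- simulate_pca(params, 40, 40, 20, seed = 42)
  b <- simulate_pca(params, 40, 40, 20, seed = 42)
  expect_identical(unclass(a)[seq_along(a)], unclass(b)[seq_along(b)])

  init <- random_lattice(40, 40, 0.2, seed = 3)
  same <- simulate_pca(params, n_steps = 0, init = init, seed = 1)
  expect_identical(unclass(same)[seq_along(same)],
                   unclass(init)[seq_along(init)])
})

test_that("banding run forms bands perpendicular to theta with wavelength
           near twice the offset, and stationarity holds late in the run", {
  params <- benchmark_params()
  sim <- simulate_pca(params, 100, 100, 600, seed = 12, record = "stats",
                      classes = build_distance_classes(10), record_stride = 5)
  # banded, self-sustaining population
  expect_gt(occupancy(sim$final), 0.15)
  bm <- estimate_band_metrics(sim$final)
  expect_false(bm$low_confidence)
  # band normal along theta (mod pi)
  expect_lt(abs(bm$orientation - params$theta %% pi), 0.25)
  # stationary spacing is close to twice the competition offset: a band
  # suppresses recruitment a distance r downstream, so stable bands sit at
  # spacing ~2r with the kill zone mid-gap
  expect_lt(abs(bm$wavelength - 2 * params$r) / (2 * params$r), 0.3)

  # population-fraction drift over the last 20% of the run is
  # indistinguishable from 0 at 3 sd of the slope estimate
  tail_rows <- sim$stats[sim$stats$step >= 0.8 * 600, ]
  fitl <- stats::lm(occupied_fraction ~ step, data = tail_rows)
  slope <- summary(fitl)$coefficients["step", ]
  expect_lt(abs(slope["Estimate"]), 3 * slope["Std. Error"])
})

test_that("zero offset with strong short-range competition drives the
           population extinct", {
  params <- model_params(sigma1 = 0.6, sigma2 = 0.6, c = 5, r = 0, theta = 0)
  out <- simulate_pca(params, 60, 60, 200, seed = 2)
  expect_identical(occupancy(out), 0)
})
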