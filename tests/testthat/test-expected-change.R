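test_that("fast expected change equals the brute-force oracle on random
           instances", {
  set.seed(17)
  dc <- build_distance_classes(3)
  for (i in 1:30) {
    lat <- random_lattice(8, 8, runif(1, 0.15, 0.85))
    params <- small_random_params(8)
    fast <- xi_matrix(expected_pair_change(lat, params, dc))
    slow <- xi_matrix(brute_force_expected_change(lat, params, dc))
    scale <- max(abs(slow), 1e-12)
    expect_lt(max(abs(fast - slow)) / scale, 1e-10)
  }
})

test_that("expected change vanishes on an empty lattice and respects
           conservation", {
  dc <- build_distance_classes(4)
  empty <- binary_lattice(matrix(0L, 12, 12), "periodic")
  params <- model_params(sigma1 = 0.5, sigma2 = 0.6, c = 1, r = 0.5,
                         theta = 0.7)
  expect_true(all(xi_matrix(expected_pair_change(empty, params, dc)) == 0))

  set.seed(8)
  for (i in 1:10) {
    lat <- random_lattice(15, 15, runif(1, 0.1, 0.9))
    p <- small_random_params(15)
    xi <- expected_pair_change(lat, p, dc)
    N_d <- 225 * dc$sizes
    expect_true(all(abs(xi$xi00 + xi$xi01 + xi$xi11) < 1e-9 * N_d))
  }
})

test_that("exhaustive enumeration of a 2x2 occupied block matches hand
           bookkeeping", {
  # all 16 states of the top-left 2x2 block of a 4x4 periodic lattice, with
  # the smallest usable kernels; the oracle recounts pairs from scratch and
  # must agree exactly with the closed-form fast path
  dc <- build_distance_classes(1)
  params <- model_params(sigma1 = 0.25, sigma2 = 0.25, c = 0.7, r = 0,
                         theta = 0)
  for (state in 0:15) {
    g <- matrix(0L, 4, 4)
    g[1:2, 1:2] <- matrix(as.integer(intToBits(state)[1:4]), 2, 2)
    lat <- binary_lattice(g, "periodic")
    fast <- xi_matrix(expected_pair_change(lat, params, dc))
    slow <- xi_matrix(brute_force_expected_change(lat, params, dc))
    expect_equal(fast, slow, tolerance = 1e-12)
  }
  # hand check: single occupied site, lam = 1, c = 0, so only births happen.
  # A birth at empty site s (rate b_s) creates one ordered 11 pair, counted
  # from each endpoint, per class-1 vector from s to the occupied site:
  # xi11(1) = 2 * sum_s b_s * n1_s(1), with n1_s enumerated directly here.
  g <- matrix(0L, 4, 4); g[1, 1] <- 1L
  lat <- binary_lattice(g, "periodic")
  p0 <- model_params(sigma1 = 0.25, sigma2 = 0.25, c = 0, r = 0, theta = 0)
  b <- as.vector(compute_rates(lat, p0)$birth)
  vs <- build_distance_classes(1)$classes[[1]]
  xi11_hand <- 0
  for (row in 1:4) for (col in 1:4) {
    if (row == 1 && col == 1) next
    n1 <- sum(((row - 1 + vs[, "dy"]) %% 4) == 0 &
                ((col - 1 + vs[, "dx"]) %% 4) == 0)
    xi11_hand <- xi11_hand + 2 * b[row + (col - 1) * 4] * n1
  }
  xi <- expected_pair_change(lat, p0, build_distance_classes(1))
  expect_equal(xi$xi11, xi11_hand, tolerance = 1e-12)
})

test_that("single occupied site gives birth rates equal to kernel weights", {
  g <- matrix(0L, 11, 11); g[6, 6] <- 1L
  lat <- binary_lattice(g, "periodic")
  params <- model_params(sigma1 = 0.9, sigma2 = 0.5, c = 1, r = 1, theta = 0)
  rates <- compute_rates(lat, params)
  k1 <- build_kernel(0.9)
  h <- attr(k1, "half_width")
  for (dy in c(-2, 0, 1)) for (dx in c(-1, 1, 2)) {
    expect_equal(rates$birth[6 + dy, 6 + dx],
                 unclass(k1)[dy + h + 1, dx + h + 1], tolerance = 1e-12)
  }
})

test_that("stationarity profile normalises recorded statistics and flags bad
           input", {
  p <- benchmark_params()
  sim <- simulate_pca(p, 40, 40, 30, seed = 3, record = "stats",
                      classes = build_distance_classes(5), record_xi = TRUE)
  prof <- stationarity_profile(sim)
  expect_identical(nrow(prof), nrow(sim$stats))
  expect_equal(as.numeric(prof[5, -1]),
               as.numeric(sim$xi[5, ] / rep(sim$N_d, each = 3)))
  expect_error(stationarity_profile(list()), "non-empty")
  sim2 <- simulate_pca(p, 40, 40, 5, seed = 3, record = "stats",
                       classes = build_distance_classes(5))
  expect_error(stationarity_profile(sim2), "record_xi")

  # trajectory route agrees with the recorded route at the final step
  traj <- simulate_pca(p, 40, 40, 10, seed = 5, record = "trajectory",
                       classes = build_distance_classes(4), record_xi = TRUE)
  prof_rec <- stationarity_profile(traj)
  prof_lat <- stationarity_profile(traj$trajectory, params = p,
                                   classes = build_distance_classes(4))
  last_rec <- sort(as.numeric(prof_rec[nrow(prof_rec), -1]))
  last_lat <- sort(as.numeric(prof_lat[nrow(prof_lat), -1]))
  expect_equal(last_rec, last_lat, tolerance = 1e-9)
})
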