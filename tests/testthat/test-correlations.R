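test_that("distance classes follow rounded Euclidean distance and exclude the
           origin", {
  dc <- build_distance_classes(4)
  # class 1: 4 axial plus 4 diagonal vectors (sqrt(2) rounds to 1)
  expect_identical(dc$sizes[1], 8L)
  all_v <- do.call(rbind, dc$classes)
  expect_false(any(all_v[, "dx"] == 0 & all_v[, "dy"] == 0))
  # every vector appears in the class of its rounded distance, exactly once
  expect_identical(nrow(all_v), nrow(unique(all_v)))
  for (d in 1:4) {
    v <- dc$classes[[d]]
    expect_true(all(round(sqrt(v[, "dx"]^2 + v[, "dy"]^2)) == d))
    # inversion symmetry
    expect_true(all(paste(-v[, "dx"], -v[, "dy"]) %in%
                      paste(v[, "dx"], v[, "dy"])))
  }
  # total count matches brute-force enumeration over the full square
  g <- expand.grid(dx = -6:6, dy = -6:6)
  expected <- sum(round(sqrt(g$dx^2 + g$dy^2)) %in% 1:4)
  expect_identical(sum(dc$sizes), expected)
  expect_error(build_distance_classes(0), "at least 1")
})

test_that("per-site neighbour counts handle full, empty and bounded corner
           cases", {
  dc <- build_distance_classes(2)
  full <- binary_lattice(matrix(1L, 7, 7), "periodic")
  cnt <- per_site_neighbor_counts(full, dc)
  expect_true(all(cnt$n1[, 1] == dc$sizes[1]))
  expect_true(all(cnt$n1[, 2] == dc$sizes[2]))
  expect_true(all(cnt$n0 == 0L))

  empty <- binary_lattice(matrix(0L, 7, 7), "periodic")
  cnt0 <- per_site_neighbor_counts(empty, dc)
  expect_true(all(cnt0$n0 == rep(dc$sizes, each = 49)))
  expect_true(all(cnt0$n1 == 0L))

  # bounded 5x5: the corner site sees only in-lattice class-1 neighbours
  b <- binary_lattice(matrix(1L, 5, 5), "bounded")
  cb <- per_site_neighbor_counts(b, build_distance_classes(1))
  # corner (1,1): in-lattice class-1 vectors are (1,0),(0,1),(1,1) -> 3
  expect_identical(cb$n_tot[1, 1], 3L)
  expect_identical(cb$n1[1, 1], 3L)
  # centre site sees all 8
  centre <- 3L + (3L - 1L) * 5L
  expect_identical(cb$n_tot[centre, 1], 8L)
})

test_that("pair counts are consistent, normalised and translation
           invariant", {
  dc <- build_distance_classes(3)
  lat <- random_lattice(20, 20, 0.35, seed = 5)
  tab <- pair_counts(lat, dc)
  expect_identical(tab$N00 + tab$N01 + tab$N11, tab$N)
  expect_equal(tab$P00 + tab$P01 + tab$P11, rep(1, 3), tolerance = 1e-12)
  expect_identical(tab$N, 400L * dc$sizes)

  # rolling the periodic lattice leaves the table unchanged
  S <- matrix(unclass(lat), 20, 20)
  rolled <- binary_lattice(S[c(8:20, 1:7), c(15:20, 1:14)], "periodic")
  expect_identical(pair_counts(rolled, dc)$N11, tab$N11)

  # per-site counts aggregate to the same totals
  cnt <- per_site_neighbor_counts(lat, dc)
  occ <- as.logical(unclass(lat))
  expect_identical(as.integer(colSums(cnt$n1[occ, ])), tab$N11)

  full <- binary_lattice(matrix(1L, 10, 10), "periodic")
  expect_true(all(pair_counts(full, dc)$P11 == 1))
})

test_that("checkerboard pairs split half opposite-state at distance 1", {
  tab <- pair_counts(checkerboard(12), build_distance_classes(1))
  # axial neighbours differ, diagonal neighbours match: P01(1) = 1/2
  expect_equal(tab$P01[1], 0.5, tolerance = 1e-12)
  expect_equal(tab$P00[1] + tab$P11[1], 0.5, tolerance = 1e-12)
})

test_that("bounded lattices require an adequate margin and use interior focal
           sites", {
  lat <- binary_lattice(matrix(rbinom(400, 1, 0.4), 20, 20), "bounded")
  dc <- build_distance_classes(3)
  expect_error(pair_counts(lat, dc, margin = 1), "margin")
  expect_error(pair_counts(lat, dc, margin = 10), "focal")
  tab <- pair_counts(lat, dc, margin = 3)
  # interior is 14x14; every focal site sees full classes (neighbours may
  # lie in the margin)
  expect_identical(tab$N, 196L * dc$sizes)
})
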