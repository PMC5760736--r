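# Shared fixtures built in code.

benchmark_params <- function() {
  model_params(sigma1 = 0.6, sigma2 = 2, c = 1, r = 10, theta = 1.5)
}

# random parameters whose kernels fit a small periodic lattice of side n
small_random_params <- function(n = 8) {
  h_max <- (n - 1) %/% 2
  s2 <- runif(1, 0.25, h_max / 4 - 0.25)
  model_params(sigma1 = runif(1, 0.3, h_max / 4),
               sigma2 = s2,
               c = runif(1, 0, 2),
               r = runif(1, 0, h_max - 4 * s2),
               theta = runif(1, 0, 2 * pi))
}

checkerboard <- function(n) {
  binary_lattice(outer(seq_len(n), seq_len(n), function(i, j) (i + j) %% 2L),
                 boundary = "periodic")
}

stripe_lattice <- function(n = 60, on = 5, off = 5) {
  binary_lattice(matrix(rep(rep(c(1L, 0L), times = c(on, off)),
                            length.out = n * n), n, n),
                 boundary = "periodic")
}

xi_matrix <- function(stats) as.matrix(stats[, c("xi00", "xi01", "xi11")])

# A tiny engine whose "likelihood" is under our control lets the sampler be
# tested against known posteriors without any lattice computation. The
# parameter values ride along inside the term objects, exactly as the cached
# convolution moments do in the real engine, so reused terms always carry
# the values they were computed from.
run_fake_mh <- function(loglik_fun, priors, n_burnin, n_samples, seed,
                        n_pilots = 2L, pilot_len = 200L) {
  eng <- list(
    birth_terms = function(sigma1) list(sigma1_sq = sigma1^2),
    death_terms = function(sigma2, r, theta)
      list(sigma2_sq = sigma2^2, r = r, theta = theta),
    xi_of = function(bt, dtm, c, lam = 1) c(bt, dtm, list(c = c)),
    loglik_of = function(xi) loglik_fun(xi),
    N_d = 1, k = 1L, margin = 0L, n_focal = 1L)
  bandinfer:::with_seed(seed, bandinfer:::mh_run(
    eng, priors, n_burnin, n_samples, target_accept = 0.25,
    adapt_block = 100L, scales = c(0.5, 1, 0.25, 1, 0.3), verbose = FALSE,
    n_pilots = n_pilots, pilot_len = pilot_len))
}

flat_priors <- function() {
  bm <- estimate_band_metrics(stripe_lattice(60, 5, 5))
  build_priors(bm, L = 60)
}

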