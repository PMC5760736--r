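#' Expected rate of change of pair counts
#'
#' The summary statistics at the heart of the synthetic likelihood. For each
#' distance class `d` and pair type `XY` in {00, 01, 11}, `xi_XY(d)` is the
#' expected instantaneous rate of change of the ordered pair count `N_XY(d)`
#' under the model's birth and death rates, considering first-order
#' transitions only (at most one site changes). At statistical stationarity
#' every `xi_XY(d)` is zero in expectation, which is what makes the deviation
#' of these statistics from zero an informative measure of how far a
#' parameter vector is from explaining the observed pattern.
#'
#' A death at occupied site `s` (rate `r0(s)`) converts each of the `n1`
#' occupied / `n0` empty neighbours of `s` at distance `d` from an 11/01 pair
#' into an 01/00 pair; a birth at empty site `s` (rate `r1(s)`) does the
#' reverse. Summing rate times pair-count change over focal sites gives, with
#' the factor 2 because each ordered pair is counted from both endpoints:
#' \deqn{\xi_{00}(d) = 2\left[\sum_{s\,occ} r_0(s) n^s_0(d) -
#'   \sum_{s\,emp} r_1(s) n^s_0(d)\right]}
#' \deqn{\xi_{11}(d) = 2\left[\sum_{s\,emp} r_1(s) n^s_1(d) -
#'   \sum_{s\,occ} r_0(s) n^s_1(d)\right]}
#' and `xi01 = -(xi00 + xi11)`, since single-site events conserve the total
#' number of pairs.
#'
#' @param lattice a [binary_lattice()].
#' @param params a [model_params()].
#' @param classes a [build_distance_classes()] result (or integer `k`).
#' @param margin interior margin over which focal sites are summed. Periodic
#'   lattices use 0; bounded snapshots need
#'   `margin >= k + kernel half-width` so that both the neighbour counts and
#'   the rates at every focal site are fully observed.
#' @param truncation_mult kernel truncation, see [build_kernel()].
#' @return an object of class `expected_change_stats`: a data frame with
#'   columns `d`, `xi00`, `xi01`, `xi11` and attributes `k`, `margin`.
#' @export
expected_pair_change <- function(lattice, params,
                                 classes = build_distance_classes(),
                                 margin = NULL, truncation_mult = 4) {
  if (is.numeric(classes)) classes <- build_distance_classes(classes)
  k <- classes$k
  periodic <- is_periodic(lattice)
  ks <- model_kernels(params, truncation_mult)
  h <- max(attr(ks$k1, "half_width"), attr(ks$k2, "half_width"))
  if (is.null(margin)) margin <- if (periodic) 0L else k + h
  margin <- as.integer(margin)
  if (periodic) margin <- 0L else if (margin < k + h)
    stop("bounded lattices need `margin` >= k + kernel half-width (",
         k + h, ")")
  S <- as_grid(lattice)
  focal <- focal_mask(nrow(S), ncol(S), margin)
  if (!any(focal)) stop("`margin` leaves no interior focal sites")
  counts <- per_site_neighbor_counts(lattice, classes)
  r1 <- params$lam * convolve_lattice(lattice, ks$k1)
  r0 <- params$c * convolve_lattice(lattice, ks$k2)
  xi_from_pieces(as.logical(S)[focal],
                 counts$n0[focal, , drop = FALSE],
                 counts$n1[focal, , drop = FALSE],
                 as.vector(r0)[focal], as.vector(r1)[focal], k, margin)
}

xi_from_pieces <- function(occ, n0, n1, r0, r1, k, margin) {
  r0o <- r0[occ]; r1e <- r1[!occ]
  xi00 <- 2 * (crossprod(n0[occ, , drop = FALSE], r0o) -
               crossprod(n0[!occ, , drop = FALSE], r1e))
  xi11 <- 2 * (crossprod(n1[!occ, , drop = FALSE], r1e) -
               crossprod(n1[occ, , drop = FALSE], r0o))
  out <- data.frame(d = seq_len(k), xi00 = as.vector(xi00),
                    xi01 = as.vector(-(xi00 + xi11)),
                    xi11 = as.vector(xi11))
  structure(out, class = c("expected_change_stats", "data.frame"),
            k = k, margin = margin)
}

#' Brute-force oracle for the expected pair change
#'
#' Computes the same statistics as [expected_pair_change()] by the direct
#' definition: for every site, apply the one-site flip, recount all ordered
#' pair counts of the flipped lattice from scratch, and accumulate
#' `rate x (count change)`. Mathematically identical to the fast path but
#' computed by an entirely independent route (direct-sum rates, naive
#' recounting), so agreement between the two is the package's core
#' correctness check. Cost grows as lattice-size squared; intended for small
#' periodic lattices (side up to about 20).
#'
#' @inheritParams expected_pair_change
#' @return an `expected_change_stats` data frame.
#' @export
brute_force_expected_change <- function(lattice, params,
                                        classes = build_distance_classes()) {
  if (is.numeric(classes)) classes <- build_distance_classes(classes)
  if (!is_periodic(lattice))
    stop("the brute-force oracle is defined for periodic lattices")
  k <- classes$k
  S <- as_grid(lattice)
  n_r <- nrow(S); n_c <- ncol(S)
  ks <- model_kernels(params)
  birth <- params$lam * convolve_direct(lattice, ks$k1)
  death <- params$c * convolve_direct(lattice, ks$k2)
  base <- naive_pair_counts(S, classes)
  xi <- matrix(0, k, 3L)
  for (idx in seq_along(S)) {
    S2 <- S
    S2[idx] <- 1L - S2[idx]
    rate <- if (S[idx] == 1L) death[idx] else birth[idx]
    if (rate == 0) next
    delta <- naive_pair_counts(S2, classes) - base
    xi <- xi + rate * delta
  }
  out <- data.frame(d = seq_len(k), xi00 = as.vector(xi[, 1L]),
                    xi01 = as.vector(xi[, 2L]), xi11 = as.vector(xi[, 3L]))
  structure(out, class = c("expected_change_stats", "data.frame"),
            k = k, margin = 0L)
}

# Ordered pair counts (N00, N01, N11) per distance class by explicit modular
# index arithmetic; deliberately shares no code with per_site_neighbor_counts.
naive_pair_counts <- function(S, classes) {
  n_r <- nrow(S); n_c <- ncol(S)
  i <- rep(seq_len(n_r), times = n_c)
  j <- rep(seq_len(n_c), each = n_r)
  s <- as.vector(S)
  out <- matrix(0, classes$k, 3L, dimnames = list(NULL, c("N00", "N01", "N11")))
  for (d in seq_len(classes$k)) {
    vs <- classes$classes[[d]]
    for (v in seq_len(nrow(vs))) {
      ii <- ((i - 1L + vs[v, "dy"]) %% n_r) + 1L
      jj <- ((j - 1L + vs[v, "dx"]) %% n_c) + 1L
      nb <- s[ii + (jj - 1L) * n_r]
      out[d, "N00"] <- out[d, "N00"] + sum(s == 0L & nb == 0L)
      out[d, "N11"] <- out[d, "N11"] + sum(s == 1L & nb == 1L)
      out[d, "N01"] <- out[d, "N01"] + sum(s != nb)
    }
  }
  out
}

#' Stationarity profile of the expected-change statistics
#'
#' Normalises recorded `xi_XY(d)` time series by the total pair count `N(d)`,
#' giving dimensionless per-pair error series that relax to zero-mean
#' fluctuations once the simulation reaches statistical stationarity. Accepts
#' either a [simulate_pca()] result recorded with `record_xi = TRUE`, or a
#' list of periodic lattices (a trajectory) plus the parameters.
#'
#' @param x a `pca_simulation` with recorded `xi`, or a list of lattices.
#' @param params required when `x` is a list of lattices.
#' @param classes distance classes used when recomputing from lattices.
#' @return data frame: `step` plus one normalised column per statistic
#'   (`xi00_1`, ..., `xi11_k`).
#' @export
stationarity_profile <- function(x, params = NULL,
                                 classes = build_distance_classes()) {
  if (inherits(x, "pca_simulation")) {
    if (is.null(x$xi))
      stop("simulation was not recorded with `record_xi = TRUE`")
    N_rep <- rep(x$N_d, each = 3L)
    return(data.frame(step = x$stats$step,
                      sweep(x$xi, 2L, N_rep, "/"), check.names = FALSE))
  }
  if (!is.list(x) || length(x) == 0L)
    stop("`x` must be a non-empty trajectory or a pca_simulation")
  if (is.null(params)) stop("`params` is required for a lattice trajectory")
  if (is.numeric(classes)) classes <- build_distance_classes(classes)
  rows <- lapply(x, function(lat) {
    xi <- expected_pair_change(lat, params, classes)
    N_d <- length(lat) * classes$sizes
    c(xi$xi00 / N_d, xi$xi01 / N_d, xi$xi11 / N_d)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c(paste0("xi00_", seq_len(classes$k)),
                   paste0("xi01_", seq_len(classes$k)),
                   paste0("xi11_", seq_len(classes$k)))
  data.frame(step = seq_along(x) - 1L, m, check.names = FALSE)
}
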