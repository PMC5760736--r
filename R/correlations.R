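#' Euclidean distance classes on the lattice
#'
#' Partitions integer displacements `(dx, dy)` into annular classes by
#' rounding the Euclidean distance `sqrt(dx^2 + dy^2)` to the nearest integer
#' (round-half-even, R's default). Class `d` collects every displacement whose
#' rounded distance is `d`, for `d = 1, ..., k`; the origin belongs to no
#' class. Classes are inversion-symmetric by construction.
#'
#' @param k maximum distance class, `k >= 1`. Default 20, enough to cover the
#'   band wavelength (about 10 lattice units) with room to spare.
#' @return an object of class `distance_classes`: a list with `k`, `classes`
#'   (list of two-column `dx, dy` integer matrices) and `sizes` (vector of
#'   class sizes).
#' @examples
#' dc <- build_distance_classes(3)
#' dc$sizes[1]  # 8: the 4 axial plus 4 diagonal neighbours round to 1
#' @export
build_distance_classes <- function(k = 20) {
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be at least 1")
  d <- seq.int(-k, k)
  dx <- as.integer(outer(rep(1L, length(d)), d))
  dy <- as.integer(outer(d, rep(1L, length(d))))
  dist <- as.integer(round(sqrt(dx^2 + dy^2)))
  keep <- dist >= 1L & dist <= k & !(dx == 0L & dy == 0L)
  dx <- dx[keep]; dy <- dy[keep]; dist <- dist[keep]
  classes <- lapply(seq_len(k), function(dd) {
    cbind(dx = dx[dist == dd], dy = dy[dist == dd])
  })
  structure(list(k = k, classes = classes, sizes = vapply(classes, nrow, 1L)),
            class = "distance_classes")
}

#' @export
print.distance_classes <- function(x, ...) {
  cat(sprintf("distance_classes: k = %d, class sizes %s\n", x$k,
              paste(x$sizes, collapse = " ")))
  invisible(x)
}

# Roll a matrix so that out[i,j] = m[i + dy, j + dx] (periodic) or the
# zero-filled shift (bounded). Used for exact integer neighbour counting.
shift_matrix <- function(m, dy, dx, periodic) {
  n_r <- nrow(m); n_c <- ncol(m)
  if (periodic) {
    rows <- ((seq_len(n_r) - 1L + dy) %% n_r) + 1L
    cols <- ((seq_len(n_c) - 1L + dx) %% n_c) + 1L
    m[rows, cols]
  } else {
    out <- matrix(0L, n_r, n_c)
    src_r <- seq_len(n_r) + dy; src_c <- seq_len(n_c) + dx
    ok_r <- src_r >= 1L & src_r <= n_r; ok_c <- src_c >= 1L & src_c <= n_c
    if (any(ok_r) && any(ok_c))
      out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
    out
  }
}

#' Per-site neighbour counts by distance class
#'
#' For every site `s` and distance class `d`, counts the observed neighbours
#' of `s` at distance `d` that are occupied (`n1`), empty (`n0`) and observed
#' at all (`n_tot`; equals the class size on a periodic lattice, fewer near
#' the edge of a bounded one, where off-lattice displacements are skipped).
#'
#' These fields depend only on the data lattice, so the fitting machinery
#' computes them once per snapshot; each subsequent likelihood evaluation is
#' then two kernel convolutions plus a handful of weighted sums.
#'
#' @param lattice a [binary_lattice()].
#' @param classes a [build_distance_classes()] result.
#' @return list with `n1`, `n0`, `n_tot`: each an `n_sites x k` integer matrix
#'   in column-major site order.
#' @export
per_site_neighbor_counts <- function(lattice, classes) {
  S <- as_grid(lattice)
  periodic <- is_periodic(lattice)
  n <- length(S)
  ones <- matrix(1L, nrow(S), ncol(S))
  k <- classes$k
  n1 <- matrix(0L, n, k); n_tot <- matrix(0L, n, k)
  for (d in seq_len(k)) {
    vs <- classes$classes[[d]]
    acc1 <- matrix(0L, nrow(S), ncol(S))
    accT <- if (periodic) NULL else matrix(0L, nrow(S), ncol(S))
    for (v in seq_len(nrow(vs))) {
      acc1 <- acc1 + shift_matrix(S, vs[v, "dy"], vs[v, "dx"], periodic)
      if (!periodic)
        accT <- accT + shift_matrix(ones, vs[v, "dy"], vs[v, "dx"], FALSE)
    }
    n1[, d] <- as.integer(acc1)
    n_tot[, d] <- if (periodic) rep.int(nrow(vs), n) else as.integer(accT)
  }
  list(n1 = n1, n0 = n_tot - n1, n_tot = n_tot)
}

# FFT-based occupied-neighbour count fields: one n_r x n_c matrix per class.
# Used inside the simulator's per-step monitoring where speed matters; counts
# are exact after rounding. `class_ffts` comes from class_kernel_ffts().
neighbor_fields_fft <- function(fft_S, class_ffts, n_r, n_c) {
  lapply(class_ffts, function(cf) {
    round(Re(stats::fft(fft_S * cf, inverse = TRUE)) / (n_r * n_c))
  })
}

class_kernel_ffts <- function(classes, n_r, n_c) {
  lapply(classes$classes, function(vs) {
    pad <- matrix(0, n_r, n_c)
    # indicator of the class, arranged for circular correlation:
    # out[s] = sum_v S[s + v]  <=>  kernel weight at displacement -v
    pad[((-vs[, "dy"]) %% n_r) + 1L + (((-vs[, "dx"]) %% n_c)) * n_r] <- 1
    stats::fft(pad)
  })
}

#' Pair counts and pair-wise correlations
#'
#' Counts ordered (directed) site pairs at each Euclidean distance class:
#' `N00(d)`, `N01(d)`, `N11(d)` and their total `N(d)`, plus the normalised
#' pair-wise correlations `P_XY(d) = N_XY(d) / N(d)`. Every unordered pair
#' whose endpoints are both focal is counted from each endpoint; `N01`
#' aggregates both the (0,1) and (1,0) orders.
#'
#' Focal sites are all sites on a periodic lattice (`margin = 0`); on a
#' bounded snapshot they are the interior sites at least `margin >= k` from
#' every edge, so that every focal site's neighbourhood is fully observed
#' (neighbours may lie in the margin). This is the boundary handling needed
#' because sites beyond an observed snapshot's edge are unknown.
#'
#' @param lattice a [binary_lattice()].
#' @param classes a [build_distance_classes()] result (or an integer `k`).
#' @param margin interior margin for bounded lattices; default `classes$k`.
#'   Forced to 0 for periodic lattices.
#' @return a `data.frame` of class `pair_count_table` with columns `d`, `N`,
#'   `N00`, `N01`, `N11`, `P00`, `P01`, `P11`; attributes `margin` and `k`.
#' @export
pair_counts <- function(lattice, classes = build_distance_classes(),
                        margin = NULL) {
  if (is.numeric(classes)) classes <- build_distance_classes(classes)
  periodic <- is_periodic(lattice)
  k <- classes$k
  if (is.null(margin)) margin <- if (periodic) 0L else k
  margin <- as.integer(margin)
  if (periodic) margin <- 0L else if (margin < k)
    stop("bounded lattices need `margin` >= k so neighbourhoods are observed")
  S <- as_grid(lattice)
  focal <- focal_mask(nrow(S), ncol(S), margin)
  if (!any(focal)) stop("`margin` leaves no interior focal sites")
  counts <- per_site_neighbor_counts(lattice, classes)
  occ <- as.logical(S)[focal]
  n1 <- counts$n1[focal, , drop = FALSE]
  n0 <- counts$n0[focal, , drop = FALSE]
  nt <- counts$n_tot[focal, , drop = FALSE]
  N11 <- as.integer(colSums(n1[occ, , drop = FALSE]))
  N00 <- as.integer(colSums(n0[!occ, , drop = FALSE]))
  N01 <- as.integer(colSums(n0[occ, , drop = FALSE]) +
                      colSums(n1[!occ, , drop = FALSE]))
  N <- as.integer(colSums(nt))
  out <- data.frame(d = seq_len(k), N = N, N00 = N00, N01 = N01, N11 = N11,
                    P00 = N00 / N, P01 = N01 / N, P11 = N11 / N)
  structure(out, class = c("pair_count_table", "data.frame"),
            margin = margin, k = k)
}

focal_mask <- function(n_r, n_c, margin) {
  if (margin == 0L) return(rep(TRUE, n_r * n_c))
  row_ok <- seq_len(n_r) > margin & seq_len(n_r) <= n_r - margin
  col_ok <- seq_len(n_c) > margin & seq_len(n_c) <= n_c - margin
  as.vector(outer(row_ok, col_ok, `&`))
}
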