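#' Construct a binary occupancy lattice
#'
#' A `binary_lattice` is the basic data object of the package: a matrix of 0s
#' and 1s recording which sites of a regular square grid are occupied by the
#' sessile organism (1) or empty (0), together with the boundary policy used
#' by all downstream computations. Simulated lattices wrap around (periodic
#' boundary); observed snapshots are `bounded`, because sites beyond the image
#' edge are simply unobserved.
#'
#' The coordinate convention used throughout the package is: the first matrix
#' index is the row `y` (increasing downward), the second is the column `x`
#' (increasing rightward); angles are measured from +x toward +y.
#'
#' @param grid numeric or integer matrix containing only 0 and 1.
#' @param boundary `"periodic"` or `"bounded"`.
#' @param cell_size optional positive number, metres per lattice unit
#'   (display/reporting only; all computations are in lattice units).
#' @return an object of class `binary_lattice`: the integer matrix with
#'   attributes `boundary` and (optionally) `cell_size`.
#' @examples
#' lat <- binary_lattice(matrix(c(0, 1, 1, 0), 2, 2))
#' occupancy(lat)
#' @export
binary_lattice <- function(grid, boundary = c("periodic", "bounded"),
                           cell_size = NULL) {
  boundary <- match.arg(boundary)
  if (!is.matrix(grid)) stop("`grid` must be a matrix")
  if (nrow(grid) < 1L || ncol(grid) < 1L) stop("`grid` must be non-empty")
  g <- suppressWarnings(as.integer(grid))
  if (anyNA(g) || any(g != 0L & g != 1L))
    stop("lattice entries must all be exactly 0 or 1")
  m <- matrix(g, nrow(grid), ncol(grid))
  structure(m, class = "binary_lattice", boundary = boundary,
            cell_size = cell_size)
}

#' @export
print.binary_lattice <- function(x, ...) {
  cat(sprintf("binary_lattice: %d x %d, %s boundary, occupancy %.3f\n",
              nrow(x), ncol(x), attr(x, "boundary"), occupancy(x)))
  invisible(x)
}

#' @rdname binary_lattice
#' @param x a `binary_lattice`.
#' @export
occupancy <- function(x) mean(unclass(x))

#' @rdname binary_lattice
#' @export
is_periodic <- function(x) identical(attr(x, "boundary"), "periodic")

as_grid <- function(x) {
  m <- unclass(x)
  attributes(m) <- list(dim = dim(m))
  m
}

#' Read a binary lattice from disk
#'
#' Reads either a plain-text 0/1 grid (whitespace- or comma-separated tokens,
#' one row per line) or an 8-bit grayscale PNG image thresholded on the
#' normalised intensity. Observed snapshots read from disk are always
#' `bounded`.
#'
#' @param path file to read.
#' @param format `"grid-text"` or `"image"`; defaults from the file extension
#'   (`.png` reads as image, anything else as grid text).
#' @param threshold for images: pixels with normalised intensity >= threshold
#'   map to occupied. Must lie in (0, 1). Default 0.5.
#' @return a bounded [binary_lattice()].
#' @export
read_lattice <- function(path, format = c("auto", "grid-text", "image"),
                         threshold = 0.5) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.png$", path, ignore.case = TRUE)) "image" else "grid-text"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "image") {
    if (!(threshold > 0 && threshold < 1))
      stop("`threshold` must lie strictly within (0, 1)")
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]  # first channel of RGB(A)
    return(binary_lattice((img >= threshold) + 0L, boundary = "bounded"))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty lattice file: ", path)
  rows <- lapply(lines, function(l) strsplit(trimws(l), "[,[:space:]]+")[[1]])
  len <- lengths(rows)
  if (length(unique(len)) != 1L)
    stop("malformed grid: rows have unequal length (", paste(unique(len), collapse = ", "), ")")
  tok <- unlist(rows)
  if (!all(tok %in% c("0", "1")))
    stop("grid entries must be 0 or 1; found: ",
         paste(utils::head(setdiff(unique(tok), c("0", "1")), 5), collapse = " "))
  m <- matrix(as.integer(tok), nrow = length(rows), ncol = len[1], byrow = TRUE)
  binary_lattice(m, boundary = "bounded")
}

#' Write a binary lattice to disk
#'
#' @param lattice a [binary_lattice()].
#' @param path destination file.
#' @param format `"grid-text"` (whitespace-separated 0/1 rows) or `"image"`
#'   (8-bit grayscale PNG, 0/255). Defaults from the extension as in
#'   [read_lattice()].
#' @return invisibly, `path`.
#' @export
write_lattice <- function(lattice, path, format = c("auto", "grid-text", "image")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.png$", path, ignore.case = TRUE)) "image" else "grid-text"
  m <- as_grid(lattice)
  if (format == "image") {
    png::writePNG(m * 1.0, target = path)
  } else {
    writeLines(apply(m, 1L, paste, collapse = " "), path)
  }
  invisible(path)
}

#' Generate a uniformly random lattice
#'
#' Each site is occupied independently with probability `occupancy`. Random
#' initial conditions of this kind (10% occupancy by default elsewhere in the
#' package) are the standard starting state for the pattern-forming
#' simulations.
#'
#' @param n_rows,n_cols lattice dimensions.
#' @param occupancy probability in \[0, 1\] that a site is occupied.
#' @param seed optional integer; when given, sampling is reproducible and the
#'   caller's RNG state is left untouched.
#' @return a periodic [binary_lattice()].
#' @export
random_lattice <- function(n_rows, n_cols, occupancy, seed = NULL) {
  if (!(occupancy >= 0 && occupancy <= 1))
    stop("`occupancy` must lie in [0, 1]")
  draw <- function() matrix(as.integer(stats::runif(n_rows * n_cols) < occupancy),
                            n_rows, n_cols)
  m <- if (is.null(seed)) draw() else with_seed(seed, draw())
  binary_lattice(m, boundary = "periodic")
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Derive a reproducible sub-seed (stage substream) from a master seed.
# Keeps results independent across pipeline stages re-run in isolation.
sub_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1009L + match(stage, c(
    "init", "simulate", "calibrate", "fit", "predict", "misc")) * 7919L
}
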