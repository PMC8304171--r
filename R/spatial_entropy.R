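#' Planar point pattern in a bounded window
#'
#' Container for strike coordinates observed in a window of known area. The
#' window defaults to the full half court, so spatial entropies are
#' comparable across matches regardless of where the strokes fall.
#'
#' @param x numeric vector of x coordinates (meters), or a two-column
#'   matrix/data frame of coordinates.
#' @param y numeric vector of y coordinates; ignored when `x` is
#'   two-dimensional.
#' @param area window area in m^2; defaults to `geom$area`.
#' @param geom a [court_geometry()] used when `area` is not given.
#' @return Object of class `point_pattern`: list with `x`, `y`, `n`, `area`.
#' @export
point_pattern <- function(x, y = NULL, area = NULL, geom = court_geometry()) {
  if (is.matrix(x) || is.data.frame(x)) {
    y <- as.numeric(x[, 2]); x <- as.numeric(x[, 1])
  }
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("coordinates must be finite")
  area <- area %||% geom$area
  if (!is.numeric(area) || length(area) != 1 || !is.finite(area) || area <= 0)
    stop("window area must be a positive number")
  structure(list(x = x, y = y, n = length(x), area = area),
            class = "point_pattern")
}

#' Nearest-neighbour distances of a point pattern
#'
#' Exact Euclidean distance from each point to its nearest other point,
#' computed by a uniform-grid search (compiled); ties are broken arbitrarily
#' and duplicated points contribute distance 0.
#'
#' @param pattern a [point_pattern()].
#' @return `nn_distances()`: numeric vector of length `n`;
#'   `mean_nn_distance()`: their arithmetic mean, the quantity `<r>`.
#' @export
nn_distances <- function(pattern) {
  if (!inherits(pattern, "point_pattern")) stop("not a point_pattern")
  if (pattern$n < 2)
    stop("at least two points are required for nearest-neighbour distances")
  .nn_dist_cpp(pattern$x, pattern$y)
}

#' @rdname nn_distances
#' @export
mean_nn_distance <- function(pattern) {
  mean(nn_distances(pattern))
}

#' Expected mean nearest-neighbour distance under spatial randomness
#'
#' For `N` points placed independently and uniformly over a window of area
#' `S` (complete spatial randomness), the expected mean nearest-neighbour
#' distance is `r_ran = (1/2) * sqrt(S / N)`.
#'
#' @param area window area `S` in m^2.
#' @param n number of points `N`.
#' @return Numeric scalar, meters.
#' @examples
#' expected_random_nn(1, 4)    # 0.25
#' expected_random_nn(100, 25) # 1
#' @export
expected_random_nn <- function(area, n) {
  if (!is.numeric(area) || any(!is.finite(area)) || any(area <= 0))
    stop("area must be positive")
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 1))
    stop("n must be a positive count")
  0.5 * sqrt(area / n)
}

#' Nearest-neighbour distance density under complete spatial randomness
#'
#' The nearest-neighbour distance of a homogeneous Poisson process of
#' intensity `density` points per m^2 has probability density
#' `p(r) = 2 * pi * density * r * exp(-pi * density * r^2)`; its mean is
#' `1 / (2 * sqrt(density))`, which matches [expected_random_nn()] with
#' `S = N / density`.
#'
#' @param r distance in meters (vectorized, `r >= 0`).
#' @param density point density in points per m^2.
#' @return Density values at `r`.
#' @export
nn_distance_density <- function(r, density) {
  if (any(!is.finite(r)) || any(r < 0)) stop("r must be non-negative")
  if (!is.numeric(density) || length(density) != 1 || density <= 0)
    stop("density must be positive")
  2 * pi * density * r * exp(-pi * density * r^2)
}

#' Clark-Evans spatial entropy of a point pattern
#'
#' The ratio `Hs = <r> / r_ran` of the observed mean nearest-neighbour
#' distance to the one expected under complete spatial randomness in the
#' same window. Interpretation: `Hs` well below 1 indicates clustering
#' (strokes concentrated in small regions), `Hs` near 1 a spatially random
#' pattern, and `Hs` approaching the triangular-lattice ceiling
#' [lattice_ceiling()] = 2.149 a regular arrangement. No edge-effect
#' correction is applied; `correction = "donnelly"` enables Donnelly's
#' boundary adjustment of the expected distance for a rectangular window.
#'
#' @param pattern a [point_pattern()] with `n >= 2`.
#' @param correction `"none"` (default) or `"donnelly"`.
#' @param perimeter window perimeter in meters, required for the Donnelly
#'   correction; defaults to the perimeter of the default court.
#' @return Object of class `spatial_entropy`: list with `Hs`, `mean_nn`,
#'   `r_ran`, `n`, `area`.
#' @examples
#' p <- point_pattern(c(0, 1, 0, 1), c(0, 0, 1, 1), area = 1)
#' spatial_entropy(p)$Hs # 4: tiny-n boundary case, each NN distance is 1
#' @export
spatial_entropy <- function(pattern, correction = c("none", "donnelly"),
                            perimeter = NULL) {
  correction <- match.arg(correction)
  mnn <- mean_nn_distance(pattern)
  r_ran <- expected_random_nn(pattern$area, pattern$n)
  if (correction == "donnelly") {
    if (is.null(perimeter)) {
      g <- court_geometry()
      perimeter <- 2 * (g$width + g$depth)
    }
    r_ran <- r_ran + (0.0514 + 0.041 / sqrt(pattern$n)) *
      perimeter / pattern$n
  }
  structure(list(Hs = mnn / r_ran, mean_nn = mnn, r_ran = r_ran,
                 n = pattern$n, area = pattern$area,
                 correction = correction),
            class = "spatial_entropy")
}

#' @export
print.spatial_entropy <- function(x, ...) {
  cat(sprintf("Spatial entropy Hs = %.4f  (<r> = %.4f m, r_ran = %.4f m, N = %d, S = %.2f m^2)\n",
              x$Hs, x$mean_nn, x$r_ran, x$n, x$area))
  invisible(x)
}

#' Regularity ceiling of the spatial entropy
#'
#' In the plane, the mean nearest-neighbour distance at fixed density is
#' maximized by the triangular (hexagonal-packing) lattice, whose spacing at
#' density `delta` is `sqrt(2 / (sqrt(3) * delta))`. Dividing by
#' `r_ran = 1 / (2 * sqrt(delta))` gives the density-free ceiling
#' `2 * sqrt(2 / sqrt(3)) = 2.1491...`.
#'
#' @return Numeric scalar.
#' @export
lattice_ceiling <- function() {
  2 * sqrt(2 / sqrt(3))
}

#' Reference pattern generators: random, lattice, clustered
#'
#' Generators for the three spatial regimes against which strike patterns
#' are interpreted: uniform-random points (`Hs` near 1), a triangular
#' lattice clipped to the court (`Hs` near the 2.149 ceiling), and
#' corner-centred Gaussian clusters (`Hs` well below 1).
#'
#' @param n,n_target number of points (for the lattice, a target; the
#'   clipped lattice lands within about 10% of it).
#' @param geom a [court_geometry()] providing the window.
#' @param seed optional integer seed for reproducible draws.
#' @param centers cluster centres, a k x 2 matrix; defaults to the four
#'   corner-zone centres.
#' @param spread isotropic Gaussian standard deviation of each cluster, in
#'   meters.
#' @return A [point_pattern()] on the court window.
#' @name reference_patterns
NULL

#' @rdname reference_patterns
#' @export
generate_random_pattern <- function(n, geom = court_geometry(), seed = NULL) {
  if (n < 2) stop("n must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  point_pattern(stats::runif(n, 0, geom$width),
                stats::runif(n, 0, geom$depth), geom = geom)
}

#' @rdname reference_patterns
#' @export
generate_lattice_pattern <- function(n_target, geom = court_geometry()) {
  if (n_target < 4) stop("n_target must be at least 4")
  # spacing of the triangular lattice whose ideal density is n_target / area
  d <- sqrt(2 * geom$area / (sqrt(3) * n_target))
  margin <- d / 2
  ys <- seq(margin, geom$depth - margin, by = d * sqrt(3) / 2)
  pts <- lapply(seq_along(ys), function(k) {
    off <- if (k %% 2 == 0) d / 2 else 0
    xs <- seq(margin + off, geom$width - margin, by = d)
    cbind(xs, ys[k])
  })
  pts <- do.call(rbind, pts)
  point_pattern(pts[, 1], pts[, 2], geom = geom)
}

#' @rdname reference_patterns
#' @export
generate_clustered_pattern <- function(n, centers = NULL, spread = 0.4,
                                       geom = court_geometry(), seed = NULL) {
  if (n < 2) stop("n must be at least 2")
  if (!is.numeric(spread) || spread <= 0) stop("spread must be positive")
  if (!is.null(seed)) set.seed(seed)
  centers <- centers %||% corner_centres(geom)
  centers <- as.matrix(centers)
  k <- nrow(centers)
  idx <- rep(seq_len(k), length.out = n)          # equal allocation
  x <- centers[idx, 1] + stats::rnorm(n, 0, spread)
  y <- centers[idx, 2] + stats::rnorm(n, 0, spread)
  point_pattern(pmin(pmax(x, 0), geom$width),
                pmin(pmax(y, 0), geom$depth), geom = geom)
}

#' Export / import a point pattern as CSV plus sidecar JSON
#'
#' The coordinates go to a two-column CSV (`x`, `y`); the window metadata
#' (`area`, `n`) to `<path>.json`.
#'
#' @param pattern a [point_pattern()].
#' @param path CSV path; the sidecar is written at `paste0(path, ".json")`.
#' @return `write_point_pattern()` the path, invisibly;
#'   `read_point_pattern()` the reconstructed pattern.
#' @export
write_point_pattern <- function(pattern, path) {
  utils::write.csv(data.frame(x = pattern$x, y = pattern$y), path,
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(area = pattern$area, n = pattern$n),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_point_pattern
#' @export
read_point_pattern <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  point_pattern(df$x, df$y, area = meta$area)
}
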