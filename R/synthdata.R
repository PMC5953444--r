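#' Angular sector specification
#'
#' A set of closed parametric-angle intervals selecting parts of an
#' ellipse boundary.  Intervals are given in degrees at the interface and
#' stored in radians; each interval must lie within `[-180, 360)` degrees
#' and have positive length.
#'
#' @param ... Numeric vectors of length 2 (`c(lo, hi)` in degrees), or a
#'   single matrix/list of such intervals.
#' @return An object of class `"sector_spec"`: a 2-column matrix of
#'   interval bounds in radians.
#' @examples
#' sector_spec(c(-60, 60), c(120, 240))
#' @export
sector_spec <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]])) args <- args[[1]]
  if (length(args) == 1L && is.matrix(args[[1]]))
    args <- asplit(args[[1]], 1)
  if (length(args) == 0L) stop("sector specification must be non-empty")
  iv <- do.call(rbind, lapply(args, function(r) {
    r <- as.numeric(r)
    if (length(r) != 2L || !all(is.finite(r)) || r[2] <= r[1])
      stop("each interval must be c(lo, hi) in degrees with lo < hi")
    if (r[1] < -180 || r[2] >= 360 + 1e-9)
      stop("intervals must lie within [-180, 360) degrees")
    r
  }))
  structure(iv * pi / 180, class = "sector_spec",
            dimnames = list(NULL, c("lo", "hi")))
}

#' The five benchmark angular sector ranges
#'
#' The standard sector ranges used throughout the benchmarking harness,
#' ordered from the widest (range1) to the narrowest (range5).  All are
#' symmetric about the two ends of the major axis:
#' range1 `[-60, 60] + [120, 240]`, range2 `[-30, 30] + [150, 210]`,
#' range3 `[-15, 15] + [165, 195]`, range4 `[-8, 8] + [172, 188]`,
#' range5 `[-4, 4] + [176, 184]` (degrees of parametric angle).
#'
#' @return Named list of `"sector_spec"` objects.
#' @export
benchmark_sectors <- function() {
  list(
    range1 = sector_spec(c(-60, 60), c(120, 240)),
    range2 = sector_spec(c(-30, 30), c(150, 210)),
    range3 = sector_spec(c(-15, 15), c(165, 195)),
    range4 = sector_spec(c(-8, 8), c(172, 188)),
    range5 = sector_spec(c(-4, 4), c(176, 184))
  )
}

#' Sample points on an ellipse within angular sectors
#'
#' Draws `n` parametric angles i.i.d. uniformly over the union of the
#' sector intervals (intervals weighted by their length) and maps them to
#' the ellipse boundary.  The sampled angles are attached as the
#' `"angles"` attribute.
#'
#' @param e An `"ellipse"` object.
#' @param spec A `"sector_spec"`; defaults to the full boundary.
#' @param n Number of points, `>= 1`.
#' @param seed Optional integer seed for reproducibility; when `NULL` the
#'   current RNG state is used.
#' @return An `n x 2` matrix with columns `x`, `y` and attribute
#'   `"angles"`.
#' @examples
#' e <- ellipse(0, 0, 100, 32)
#' p <- sample_sector(e, benchmark_sectors()$range1, 100, seed = 1)
#' mean_point_eccentricity(p, e)
#' @export
sample_sector <- function(e, spec = sector_spec(c(0, 360)), n, seed = NULL) {
  stopifnot(inherits(e, "ellipse"), inherits(spec, "sector_spec"))
  if (n < 1) stop("n must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  len <- spec[, 2] - spec[, 1]
  k <- sample.int(nrow(spec), n, replace = TRUE, prob = len)
  t <- stats::runif(n, spec[k, 1], spec[k, 2])
  p <- boundary_points(e, t)
  attr(p, "angles") <- t
  p
}

#' Add Gaussian noise to a point set
#'
#' Perturbs each coordinate independently by zero-mean Gaussian noise.
#' By default `sigma` is normalized: the standard deviation is
#' `sigma * a`, a fraction of the reference ellipse's semi-major axis.
#' With `normalized = FALSE`, `sigma` is an absolute standard deviation
#' and no reference ellipse is needed.
#'
#' @param p Point set (matrix or data frame).
#' @param e Reference `"ellipse"` supplying the semi-major axis; only
#'   used when `normalized = TRUE`.
#' @param sigma Noise level (`>= 0`).
#' @param normalized Interpret `sigma` as a fraction of the semi-major
#'   axis (default) or as an absolute standard deviation.
#' @param seed Optional integer seed.
#' @return Point matrix of the same size; angle annotations are retained.
#' @export
add_noise <- function(p, e = NULL, sigma, normalized = TRUE, seed = NULL) {
  xy <- as_xy(p)
  if (sigma < 0) stop("sigma must be non-negative")
  if (normalized) {
    stopifnot(inherits(e, "ellipse"))
    sigma <- sigma * e$a
  }
  if (!is.null(seed)) set.seed(seed)
  if (sigma > 0)
    xy <- xy + matrix(stats::rnorm(2 * nrow(xy), 0, sigma), ncol = 2)
  colnames(xy) <- c("x", "y")
  attr(xy, "angles") <- attr(p, "angles")
  xy
}

#' Fourfold reflective symmetrization of first-quadrant points
#'
#' Reflects a set of first-quadrant points about the x-axis, then
#' reflects both sets about the y-axis, producing `4N` points whose
#' centroid is exactly the origin.  Used to construct data whose best
#' axis-aligned fit is centred at the origin, so that all fitting error
#' lives in the semi-axis estimates.
#'
#' @param p Points in the closed first quadrant (`x >= 0`, `y >= 0`).
#' @return A `4N x 2` matrix (original, x-reflected, y-reflected, both).
#' @examples
#' symmetric_quadruple(matrix(c(1, 0.5), 1, 2))
#' @export
symmetric_quadruple <- function(p) {
  xy <- as_xy(p)
  if (any(xy < 0))
    stop("all points must lie in the closed first quadrant")
  out <- rbind(xy,
               cbind(xy[, 1], -xy[, 2]),
               cbind(-xy[, 1], xy[, 2]),
               cbind(-xy[, 1], -xy[, 2]))
  colnames(out) <- c("x", "y")
  out
}

#' Sample an occluded elliptical arc
#'
#' Emulates a tracked trajectory with a single contiguous occlusion: the
#' visible part of the boundary is a closed arc of angular length
#' `visible_fraction * 360` degrees, sampled at the spacing of `n`
#' equally spaced full-ring positions, then perturbed by noise.  With
#' `visible_fraction < 1` the arc carries `floor(visible_fraction * n) + 1`
#' points (both arc endpoints included); with `visible_fraction = 1` it is
#' the full ring of `n` points.
#'
#' @param e An `"ellipse"` object.
#' @param visible_fraction Fraction of the boundary that is visible,
#'   in `(0, 1]`.
#' @param gap_position Parametric angle (radians) at which the gap starts.
#' @param n Number of full-ring sample positions.
#' @param sigma Normalized noise level (fraction of the semi-major axis).
#' @param seed Optional integer seed.
#' @return Point matrix with attribute `"angles"`.
#' @export
occluded_arc <- function(e, visible_fraction = 1, gap_position = 0, n,
                         sigma = 0, seed = NULL) {
  stopifnot(inherits(e, "ellipse"))
  if (visible_fraction <= 0 || visible_fraction > 1)
    stop("visible_fraction must be in (0, 1]")
  if (visible_fraction == 1) {
    t <- gap_position + 2 * pi * (seq_len(n) - 1) / n
  } else {
    m <- floor(visible_fraction * n) + 1
    gap_end <- gap_position + (1 - visible_fraction) * 2 * pi
    t <- gap_end + visible_fraction * 2 * pi * (seq_len(m) - 1) / (m - 1)
  }
  p <- boundary_points(e, t)
  attr(p, "angles") <- t
  if (sigma > 0) p <- add_noise(p, e, sigma, seed = seed)
  p
}

#' Write / read a point set as CSV
#'
#' Plain two-column CSV with header `x,y`; an optional
#' `source_interval` column carries augmentation provenance.
#'
#' @param p Point matrix (optionally with a `"source_interval"` attribute).
#' @param path File path.
#' @return `read_points` returns a point matrix; `write_points` returns
#'   `path` invisibly.
#' @export
write_points <- function(p, path) {
  xy <- as_xy(p)
  df <- data.frame(x = xy[, 1], y = xy[, 2])
  src <- attr(p, "source_interval")
  if (!is.null(src)) df$source_interval <- src
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_points
#' @export
read_points <- function(path) {
  df <- utils::read.csv(path)
  p <- as_xy(df[, c("x", "y")])
  if ("source_interval" %in% names(df))
    attr(p, "source_interval") <- df$source_interval
  p
}
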