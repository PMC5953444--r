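#' Eccentricity weights for a point set
#'
#' Assigns each point the weight `w = exp(xi)`, where `xi` is its point
#' eccentricity relative to an axis estimate (see [point_eccentricity()]),
#' together with the normalized weights `W = w / sum(w)`.  Points far out
#' along the major axis carry the largest weights.
#'
#' @param p Point set (matrix or data frame).
#' @param e An `"ellipse"` supplying the axes and orientation used to
#'   compute point eccentricities; only its centre, axis ratio and
#'   orientation matter.
#' @return An object of class `"weighted_points"`: a list with `points`,
#'   `xi`, `w`, `W` and `ellipse`.
#' @export
compute_weights <- function(p, e) {
  stopifnot(inherits(e, "ellipse"))
  xy <- as_xy(p)
  xi <- point_eccentricity(xy, e)
  w <- exp(xi)
  structure(list(points = xy, xi = xi, w = w, W = w / sum(w), ellipse = e),
            class = "weighted_points")
}

#' @export
print.weighted_points <- function(x, ...) {
  cat("Weighted point set: ", nrow(x$points), " points, xi in [",
      format(min(x$xi), digits = 4), ", ", format(max(x$xi), digits = 4),
      "]\n", sep = "")
  invisible(x)
}

#' Estimate ellipse axes for weighting
#'
#' Provides the axis estimate needed by [compute_weights()] when the true
#' ellipse is unknown.  Strategy `"ensemble_mean"` fits the point set with
#' several methods and averages the geometric parameters of the converged
#' fits (`theta` averaged as a direction modulo `pi`); `"two_pass"` simply
#' returns the fit of a single named method, to be refitted after
#' augmentation.  The downstream weights are insensitive to small errors
#' in this estimate.
#'
#' @param p Point set.
#' @param strategy `"ensemble_mean"` or `"two_pass"`.
#' @param methods Methods to ensemble over (default: all five), or the
#'   single method for `"two_pass"`.
#' @return An `"ellipse"` object.
#' @export
estimate_axes <- function(p, strategy = c("ensemble_mean", "two_pass"),
                          methods = NULL) {
  strategy <- match.arg(strategy)
  xy <- as_xy(p)
  if (strategy == "two_pass") {
    method <- methods %||% "direct"
    if (length(method) != 1L)
      stop("two_pass requires a single method")
    fit <- fit_ellipse(xy, method = method)
    if (!fit$converged) stop("no axis estimate: the fit failed")
    return(fit$ellipse)
  }
  methods <- methods %||% ellipse_fit_methods()
  fits <- lapply(methods, function(m) fit_ellipse(xy, method = m))
  ok <- Filter(function(f) f$converged, fits)
  if (length(ok) == 0L) stop("no axis estimate: all fits failed")
  cf <- t(vapply(ok, coef, numeric(5)))
  # average orientation as a direction modulo pi (angle doubling)
  th <- atan2(mean(sin(2 * cf[, "theta"])), mean(cos(2 * cf[, "theta"]))) / 2
  ellipse(mean(cf[, "cx"]), mean(cf[, "cy"]),
          a = mean(cf[, "a"]), b = mean(cf[, "b"]), theta = th)
}

#' Augment a weighted point set by systematic resampling
#'
#' The data-augmentation resampler.  Points are ordered by polar angle
#' about the weighting ellipse's centre (the sequence is started at the
#' largest angular gap, so adjacency never crosses the widest void, and
#' the curve is treated as closed when the data span more than 300
#' degrees).  The cumulative distribution of the normalized weights is
#' traversed with the fixed step `1/T`, `T = floor(1 / min(W))` (capped at
#' `10 S`): every traversal step landing in the angular interval ending at
#' point `X_s` contributes one output point, so intervals around
#' high-weight (high-eccentricity) points receive extra points, created by
#' linear interpolation between `X_s` and its predecessor.  All original
#' points are always retained, and every output point carries the uniform
#' weight `1/T_out`.
#'
#' @param wp A `"weighted_points"` object from [compute_weights()].
#' @return An object of class `"augmented_points"`: a list with `points`
#'   (the output matrix, ordered along the curve, with attribute
#'   `"source_interval"`), `z` (uniform output weights), `steps` (the
#'   traversal step count `T`), `interval_counts` (traversal steps per
#'   interval), `order` (the permutation of the input rows that ordered
#'   them along the curve), `closed`, and the input `weights`.
#' @export
augment_points <- function(wp) {
  stopifnot(inherits(wp, "weighted_points"))
  xy <- wp$points
  S <- nrow(xy)
  if (S < 2L) stop("at least 2 points are required for augmentation")
  e <- wp$ellipse

  ang <- atan2(xy[, 2] - e$cy, xy[, 1] - e$cx) %% (2 * pi)
  if (anyDuplicated(ang))
    stop("points with duplicate polar angles cannot be ordered")
  ord <- order(ang)
  ang <- ang[ord]
  # start the sequence just after the largest circular gap
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  cut <- which.max(gaps)
  if (cut < S) ord <- ord[c((cut + 1):S, 1:cut)]
  xy <- wp$points[ord, , drop = FALSE]
  W <- wp$W[ord]
  span <- 2 * pi - max(gaps)
  closed <- span > 300 * pi / 180

  Tn <- max(min(floor(1 / min(W)), 10L * S), S)
  cw <- cumsum(W)
  cw[S] <- 1   # guard against round-off at the top of the distribution
  mu <- seq_len(Tn) / Tn

  cnt <- integer(S)
  s <- 1L
  for (t in seq_len(Tn)) {
    while (mu[t] > cw[s] + 1e-12 && s < S) s <- s + 1L
    cnt[s] <- cnt[s] + 1L
  }

  out <- vector("list", S)
  src <- vector("list", S)
  for (s in seq_len(S)) {
    k <- max(cnt[s] - 1L, 0L)                 # interpolated insertions
    if (s == 1L && !closed) k <- 0L           # open arc: no predecessor
    if (k > 0L) {
      prev <- if (s == 1L) xy[S, ] else xy[s - 1L, ]
      lam <- seq_len(k) / (k + 1L)
      ins <- cbind(prev[1] + lam * (xy[s, 1] - prev[1]),
                   prev[2] + lam * (xy[s, 2] - prev[2]))
      out[[s]] <- rbind(ins, xy[s, , drop = FALSE])
    } else {
      out[[s]] <- xy[s, , drop = FALSE]
    }
    src[[s]] <- rep.int(s, nrow(out[[s]]))
  }
  pts <- do.call(rbind, out)
  colnames(pts) <- c("x", "y")
  src <- unlist(src)
  attr(pts, "source_interval") <- src
  structure(list(points = pts, z = rep(1 / nrow(pts), nrow(pts)),
                 steps = Tn, interval_counts = cnt, order = ord,
                 closed = closed, weights = wp),
            class = "augmented_points")
}

#' @export
print.augmented_points <- function(x, ...) {
  cat("Augmented point set: ", nrow(x$weights$points), " -> ",
      nrow(x$points), " points (", x$steps, " traversal steps, ",
      if (x$closed) "closed" else "open", " curve)\n", sep = "")
  invisible(x)
}

#' Eccentricity-weighted augmentation pre-processing
#'
#' Composition of the pre-processing pipeline: estimate (or accept) the
#' ellipse axes, weight the points by their eccentricity, and augment the
#' set by systematic resampling.  The returned point set is ready for a
#' second-pass fit.
#'
#' @param p Point set.
#' @param axis An `"ellipse"` with the axes to weight against, or `NULL`
#'   to estimate them from the data.
#' @param axis_strategy Passed to [estimate_axes()] when `axis` is `NULL`.
#' @param method Fitting method used by the `"two_pass"` strategy (and as
#'   the ensemble default set otherwise).
#' @return An `"augmented_points"` object; its `points` component is the
#'   augmented set.
#' @examples
#' e0 <- ellipse(0, 0, 100, 32)
#' p <- add_noise(sample_sector(e0, benchmark_sectors()$range1, 100, seed = 1),
#'                e0, 0.2, seed = 2)
#' aug <- preprocess_points(p, axis = e0)
#' nrow(aug$points) >= nrow(p)
#' @export
preprocess_points <- function(p, axis = NULL,
                              axis_strategy = c("ensemble_mean", "two_pass"),
                              method = "direct") {
  xy <- as_xy(p)
  if (is.null(axis)) {
    axis_strategy <- match.arg(axis_strategy)
    axis <- estimate_axes(xy, strategy = axis_strategy,
                          methods = if (axis_strategy == "two_pass") method
                                    else NULL)
  }
  stopifnot(inherits(axis, "ellipse"))
  aug <- augment_points(compute_weights(xy, axis))
  aug$axis <- axis
  aug
}
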