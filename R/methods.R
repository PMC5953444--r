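#' Points on an ellipse boundary at given parametric angles
#'
#' @param e An `"ellipse"` object.
#' @param t Parametric angles in radians.
#' @return An `n x 2` matrix with columns `x`, `y`.
#' @export
boundary_points <- function(e, t) {
  stopifnot(inherits(e, "ellipse"))
  ct <- cos(e$theta); st <- sin(e$theta)
  u <- e$a * cos(t); v <- e$b * sin(t)
  cbind(x = e$cx + u * ct - v * st,
        y = e$cy + u * st + v * ct)
}

#' @export
print.ellipse_fit <- function(x, digits = 6, ...) {
  cat("Ellipse fit (method: ", x$method, ")\n", sep = "")
  if (x$converged) {
    print(x$ellipse, digits = digits)
  } else {
    cat("Fit failed:", x$message %||% "no ellipse", "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
coef.ellipse_fit <- function(object, ...) {
  if (!object$converged) return(c(cx = NA, cy = NA, a = NA, b = NA, theta = NA))
  with(object$ellipse, c(cx = cx, cy = cy, a = a, b = b, theta = theta))
}

#' @export
summary.ellipse_fit <- function(object, ...) {
  res <- if (object$converged) residuals(object) else numeric(0)
  out <- list(
    method = object$method,
    converged = object$converged,
    iterations = object$iterations,
    n = nrow(object$data),
    n_fit = if (is.null(object$augmented)) nrow(object$data)
            else nrow(object$augmented$points),
    augmented = !is.null(object$augmented),
    coefficients = coef(object),
    eccentricity = if (object$converged)
      ellipse_eccentricity(object$ellipse$a, object$ellipse$b) else NA_real_,
    rmse = if (object$converged) sqrt(mean(res^2)) else NA_real_,
    mean_xi = if (object$converged)
      mean_point_eccentricity(object$data, object$ellipse) else NA_real_
  )
  class(out) <- "summary.ellipse_fit"
  out
}

#' @export
print.summary.ellipse_fit <- function(x, digits = 6, ...) {
  cat("Ellipse fit, method '", x$method, "'",
      if (x$augmented) " (eccentricity-augmented pre-processing)", "\n",
      sep = "")
  cat("Points: ", x$n,
      if (x$augmented) paste0(" (", x$n_fit, " after augmentation)"),
      "\n", sep = "")
  if (!x$converged) {
    cat("Fit did not converge to an ellipse.\n")
    return(invisible(x))
  }
  cat("Parameters:\n")
  print(round(x$coefficients, digits))
  cat("Eccentricity: ", format(x$eccentricity, digits = digits), "\n", sep = "")
  cat("Mean point eccentricity of data: ",
      format(x$mean_xi, digits = digits), "\n", sep = "")
  cat("RMSE (orthogonal distance, original points): ",
      format(x$rmse, digits = digits), "\n", sep = "")
  if (!is.na(x$iterations))
    cat("Iterations: ", x$iterations, "\n", sep = "")
  invisible(x)
}

#' Residuals of an ellipse fit
#'
#' Signed orthogonal distances of the original data points to the fitted
#' ellipse boundary: positive outside the ellipse, negative inside.
#'
#' @param object An `"ellipse_fit"`.
#' @param ... Unused.
#' @return Numeric vector of signed distances.
#' @export
residuals.ellipse_fit <- function(object, ...) {
  if (!object$converged) stop("fit did not produce an ellipse")
  e <- object$ellipse
  d <- orthogonal_distance(object$data, e)
  uv <- to_ellipse_frame(object$data, e)
  inside <- (uv[, 1] / e$a)^2 + (uv[, 2] / e$b)^2 < 1
  ifelse(inside, -d, d)
}

#' @export
fitted.ellipse_fit <- function(object, ...) {
  if (!object$converged) stop("fit did not produce an ellipse")
  ellipse_project(object$data, object$ellipse)$foot
}

#' Predict boundary points of a fitted ellipse
#'
#' @param object An `"ellipse_fit"`.
#' @param t Parametric angles (radians) at which to evaluate the boundary;
#'   defaults to 360 equally spaced angles.
#' @param ... Unused.
#' @return Matrix of boundary coordinates.
#' @export
predict.ellipse_fit <- function(object, t = seq(0, 2 * pi, length.out = 361),
                                ...) {
  if (!object$converged) stop("fit did not produce an ellipse")
  boundary_points(object$ellipse, t)
}

#' Plot a fitted ellipse over its data
#'
#' @param x An `"ellipse_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ellipse_fit <- function(x, ...) {
  p <- x$data
  args <- list(...)
  if (is.null(args$xlab)) args$xlab <- "x"
  if (is.null(args$ylab)) args$ylab <- "y"
  if (is.null(args$asp)) args$asp <- 1
  do.call(graphics::plot, c(list(p[, 1], p[, 2]), args))
  if (!is.null(x$augmented)) {
    ap <- as_xy(x$augmented$points)
    graphics::points(ap[, 1], ap[, 2], pch = 3, col = "grey60", cex = 0.6)
  }
  if (x$converged) {
    bp <- predict(x)
    graphics::lines(bp[, 1], bp[, 2], col = "red", lwd = 2)
  }
  invisible(x)
}

#' Simulate noisy point sets from a fitted ellipse
#'
#' Draws point sets from the fitted ellipse boundary, uniform in
#' parametric angle, with isotropic Gaussian noise whose standard
#' deviation is `sigma` times the fitted semi-major axis.
#'
#' @param object An `"ellipse_fit"`.
#' @param nsim Number of point sets.
#' @param seed Optional RNG seed.
#' @param n Points per set; defaults to the size of the original data.
#' @param sigma Noise level as a fraction of the semi-major axis.
#' @param ... Unused.
#' @return A list of `n x 2` matrices.
#' @export
simulate.ellipse_fit <- function(object, nsim = 1, seed = NULL,
                                 n = nrow(object$data), sigma = 0, ...) {
  if (!object$converged) stop("fit did not produce an ellipse")
  if (!is.null(seed)) set.seed(seed)
  e <- object$ellipse
  spec <- sector_spec(c(0, 360))
  lapply(seq_len(nsim), function(i) {
    p <- sample_sector(e, spec, n)
    if (sigma > 0) p <- add_noise(p, e, sigma) else p
  })
}
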