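#' Construct an ellipse in geometric (parametric) form
#'
#' An ellipse is stored by its centre `(cx, cy)`, semi-major axis `a`,
#' semi-minor axis `b` and the orientation `theta` of the major axis
#' relative to the x-axis.  `theta` is normalised to `[0, pi)`; if `b > a`
#' the axes are swapped and `theta` rotated by `pi/2` so that `a >= b`
#' always holds.
#'
#' @param cx,cy Centre coordinates.
#' @param a,b Semi-axes; both must be strictly positive.  They need not be
#'   ordered: the constructor stores the larger one as the major axis.
#' @param theta Orientation of the major axis in radians.  Any real value
#'   is accepted and reduced modulo `pi`.
#' @return An object of class `"ellipse"`: a list with elements `cx`, `cy`,
#'   `a`, `b`, `theta`.
#' @examples
#' e <- ellipse(0, 0, a = 1, b = 0.32)
#' ellipse_eccentricity(e$a, e$b)
#' @seealso [as_conic()], [point_eccentricity()], [orthogonal_distance()]
#' @export
ellipse <- function(cx = 0, cy = 0, a = 1, b = 1, theta = 0) {
  stopifnot(is.numeric(cx), is.numeric(cy), is.numeric(a), is.numeric(b),
            is.numeric(theta), length(a) == 1L, length(b) == 1L)
  if (!all(is.finite(c(cx, cy, a, b, theta))))
    stop("ellipse parameters must be finite")
  if (a <= 0 || b <= 0)
    stop("semi-axes must be strictly positive")
  if (b > a) {
    tmp <- a; a <- b; b <- tmp
    theta <- theta + pi / 2
  }
  theta <- theta %% pi
  structure(list(cx = cx, cy = cy, a = a, b = b, theta = theta),
            class = "ellipse")
}

#' @export
print.ellipse <- function(x, digits = 6, ...) {
  cat("Ellipse: centre (", format(x$cx, digits = digits), ", ",
      format(x$cy, digits = digits), "), a = ", format(x$a, digits = digits),
      ", b = ", format(x$b, digits = digits),
      ", theta = ", format(x$theta, digits = digits), " rad",
      ", eccentricity = ",
      format(ellipse_eccentricity(x$a, x$b), digits = digits), "\n", sep = "")
  invisible(x)
}

#' Construct general conic coefficients
#'
#' The conic is `A x^2 + B x y + C y^2 + D x + E y + F = 0`.  Coefficients
#' are meaningful only up to a global nonzero scale.
#'
#' @param A,B,C,D,E,F Real coefficients; not all of `A`, `B`, `C` may be zero.
#' @return An object of class `"conic"`: a named numeric vector.
#' @examples
#' conic(1, 0, 1, 0, 0, -1)  # unit circle
#' @export
conic <- function(A, B, C, D, E, F) {
  v <- c(A = A, B = B, C = C, D = D, E = E, F = F)
  stopifnot(is.numeric(v), length(v) == 6L)
  if (!all(is.finite(v))) stop("conic coefficients must be finite")
  if (all(v[1:3] == 0)) stop("A, B, C must not all be zero")
  structure(v, class = "conic")
}

#' @export
print.conic <- function(x, digits = 6, ...) {
  cat("Conic coefficients (A, B, C, D, E, F):\n")
  print(format(unclass(x), digits = digits), quote = FALSE)
  invisible(x)
}

#' Eccentricity of an ellipse from its semi-axes
#'
#' Computes `sqrt(a^2 - b^2) / a` for semi-axes `a >= b`; arguments are
#' swapped internally if given in the other order.  The value is 0 for a
#' circle and approaches 1 as the ellipse degenerates towards a line.
#'
#' @param a,b Semi-axes, strictly positive.
#' @return Eccentricity in `[0, 1)`.
#' @examples
#' ellipse_eccentricity(1, 0.32)   # 0.947418
#' @export
ellipse_eccentricity <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) stop("semi-axes must be strictly positive")
  hi <- pmax(a, b)
  lo <- pmin(a, b)
  sqrt(hi^2 - lo^2) / hi
}

#' Ellipse discriminant test for a conic
#'
#' A conic is an ellipse when its discriminant `B^2 - 4AC` is negative.
#' The test is relative to the magnitude of the quadratic part so that it
#' is stable under global rescaling of the coefficients.
#'
#' @param c An object coercible to [conic()] coefficients.
#' @param tol Relative tolerance for the discriminant test.
#' @return `TRUE` iff `B^2 - 4AC < -tol * scale^2` where `scale` is the
#'   largest absolute quadratic coefficient.
#' @export
is_ellipse <- function(c, tol = 1e-12) {
  v <- as.numeric(c)
  if (length(v) != 6L || !all(is.finite(v))) stop("need 6 finite coefficients")
  scale <- max(abs(v[1:3]))
  if (scale == 0) return(FALSE)
  (v[2]^2 - 4 * v[1] * v[3]) < -tol * scale^2
}

#' Convert a parametric ellipse to conic coefficients
#'
#' Expands the geometric form into the general conic
#' `A x^2 + B x y + C y^2 + D x + E y + F = 0` and normalises the
#' coefficients so that `B^2 - 4AC = -1`.
#'
#' @param e An `"ellipse"` object.
#' @param ... Unused.
#' @return A `"conic"` object.
#' @export
as_conic <- function(e, ...) UseMethod("as_conic")

#' @rdname as_conic
#' @export
as_conic.ellipse <- function(e, ...) {
  ct <- cos(e$theta); st <- sin(e$theta)
  a2 <- e$a^2; b2 <- e$b^2
  A <- a2 * st^2 + b2 * ct^2
  B <- 2 * (b2 - a2) * st * ct
  C <- a2 * ct^2 + b2 * st^2
  D <- -2 * A * e$cx - B * e$cy
  E <- -B * e$cx - 2 * C * e$cy
  F <- A * e$cx^2 + B * e$cx * e$cy + C * e$cy^2 - a2 * b2
  # 4AC - B^2 = 4 a^2 b^2 here, so dividing by 2ab gives B^2 - 4AC = -1
  s <- 2 * e$a * e$b
  conic(A / s, B / s, C / s, D / s, E / s, F / s)
}

#' Convert conic coefficients to a parametric ellipse
#'
#' Recovers centre, semi-axes and orientation from the six coefficients of
#' a real, non-degenerate ellipse.  Signals an error for conics that are
#' not ellipses (non-negative discriminant, imaginary or degenerate cases).
#'
#' @param c A `"conic"` object or numeric vector of 6 coefficients.
#' @param ... Unused.
#' @return An `"ellipse"` object.
#' @export
as_ellipse <- function(c, ...) UseMethod("as_ellipse")

#' @rdname as_ellipse
#' @export
as_ellipse.conic <- function(c, ...) {
  v <- as.numeric(c)
  A <- v[1]; B <- v[2]; C <- v[3]; D <- v[4]; E <- v[5]; F <- v[6]
  disc <- B^2 - 4 * A * C
  if (!is_ellipse(v)) stop("not an ellipse: discriminant B^2 - 4AC >= 0")
  cx <- (2 * C * D - B * E) / disc
  cy <- (2 * A * E - B * D) / disc
  # constant term after translating the centre to the origin
  F0 <- F + (D * cx + E * cy) / 2
  M <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  ev <- eigen(M, symmetric = TRUE)
  lam <- ev$values           # decreasing order, same sign for an ellipse
  ax2 <- -F0 / lam           # semi-axis^2 along each eigen direction
  if (any(!is.finite(ax2)) || any(ax2 <= 0))
    stop("not an ellipse: imaginary or degenerate conic")
  # larger axis corresponds to the smaller |lambda| eigenvector
  i_maj <- which.max(ax2)
  vec <- ev$vectors[, i_maj]
  ellipse(cx, cy, a = sqrt(ax2[i_maj]), b = sqrt(ax2[-i_maj]),
          theta = atan2(vec[2], vec[1]))
}

#' @rdname as_ellipse
#' @export
as_ellipse.numeric <- function(c, ...) as_ellipse(do.call(conic, as.list(c)))

#' Eccentricity of an ellipse directly from conic coefficients
#'
#' Uses the closed form
#' `eps = sqrt( 2 sqrt((A-C)^2 + B^2) / (eta (A+C) + sqrt((A-C)^2 + B^2)) )`
#' where the sign `eta` is `+1` when the determinant of the full 3x3 conic
#' matrix is negative and `-1` otherwise.  Invariant under global rescaling
#' (including sign flips) of the six coefficients.
#'
#' @param c A `"conic"` object or numeric vector of 6 coefficients.
#' @return Eccentricity in `[0, 1)`.
#' @export
conic_eccentricity <- function(c) {
  v <- as.numeric(c)
  if (!is_ellipse(v)) stop("not an ellipse: discriminant B^2 - 4AC >= 0")
  A <- v[1]; B <- v[2]; C <- v[3]; D <- v[4]; E <- v[5]; F <- v[6]
  M3 <- matrix(c(A, B / 2, D / 2,
                 B / 2, C, E / 2,
                 D / 2, E / 2, F), 3, 3)
  eta <- if (det(M3) < 0) 1 else -1
  root <- sqrt((A - C)^2 + B^2)
  val <- 2 * root / (eta * (A + C) + root)
  if (!is.finite(val) || val < 0) stop("degenerate conic")
  sqrt(val)
}

# Coerce points input (matrix, data.frame with x/y, or length-2 vector)
# to an n x 2 numeric matrix.
as_xy <- function(p) {
  if (is.data.frame(p)) {
    if (all(c("x", "y") %in% names(p))) p <- cbind(p$x, p$y)
    else p <- as.matrix(p[, 1:2])
  } else if (is.numeric(p) && is.null(dim(p)) && length(p) == 2L) {
    p <- matrix(p, 1, 2)
  } else {
    p <- as.matrix(p)
  }
  storage.mode(p) <- "double"
  if (ncol(p) != 2L) stop("points must have two columns (x, y)")
  if (nrow(p) < 1L) stop("point set must contain at least one point")
  if (!all(is.finite(p))) stop("point coordinates must be finite")
  p
}

# Rotate points into the ellipse frame: columns (u, v) are coordinates
# along the major and minor axis directions, relative to the centre.
to_ellipse_frame <- function(p, e) {
  p <- as_xy(p)
  ct <- cos(e$theta); st <- sin(e$theta)
  dx <- p[, 1] - e$cx
  dy <- p[, 2] - e$cy
  cbind(u = dx * ct + dy * st, v = -dx * st + dy * ct)
}

#' Eccentricity of a data point relative to an ellipse
#'
#' For a point `X` and a candidate ellipse, let `d_a` be the orthogonal
#' distance of `X` to the ellipse's minor-axis line and `d_b` its distance
#' to the major-axis line.  The point eccentricity is
#' `xi = eps * d_a / (d_a + d_b)`, where `eps` is the ellipse
#' eccentricity.  It ranges over `[0, eps]`, is largest for points far out
#' along the major axis, and depends only on the direction of the point
#' from the centre, not on its distance.  A point exactly at the centre is
#' assigned `xi = 0` by convention.
#'
#' @param p Points: an `n x 2` matrix, a data frame with columns `x`, `y`,
#'   or a length-2 vector.
#' @param e An `"ellipse"` object.
#' @return Numeric vector of per-point eccentricities.
#' @examples
#' e <- ellipse(0, 0, 1, 0.32)
#' point_eccentricity(c(1, 0), e)  # major vertex: equals eps
#' point_eccentricity(c(0, 0.32), e)  # minor vertex: 0
#' @export
point_eccentricity <- function(p, e) {
  stopifnot(inherits(e, "ellipse"))
  uv <- to_ellipse_frame(p, e)
  da <- abs(uv[, 1])      # distance to minor-axis line
  db <- abs(uv[, 2])      # distance to major-axis line
  eps <- ellipse_eccentricity(e$a, e$b)
  xi <- eps * da / (da + db)
  xi[da + db == 0] <- 0
  unname(xi)
}

#' Mean point eccentricity of a point set
#'
#' Arithmetic mean of [point_eccentricity()] over a non-empty point set.
#'
#' @inheritParams point_eccentricity
#' @return Scalar mean eccentricity.
#' @export
mean_point_eccentricity <- function(p, e) {
  mean(point_eccentricity(p, e))
}
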