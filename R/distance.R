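#' Orthogonal projection of points onto an ellipse boundary
#'
#' Finds, for each point, the nearest point on the ellipse boundary and the
#' Euclidean distance to it.  The computation works in the ellipse frame,
#' reduces each point to the closed first quadrant by symmetry, and solves
#' the stationarity condition of the squared distance in the parametric
#' angle by Newton iteration from four starts spanning the quadrant,
#' keeping the global minimum (eccentric ellipses can have two local
#' minima).  Convergence tolerance is 1e-12 relative in angle.
#'
#' @param p Points: `n x 2` matrix, data frame with `x`/`y`, or length-2
#'   vector.
#' @param e An `"ellipse"` object.
#' @return A list with components `distance` (numeric vector, `>= 0`),
#'   `foot` (`n x 2` matrix of nearest boundary points in the original
#'   coordinates) and `t` (parametric angle of the foot point).
#' @export
ellipse_project <- function(p, e) {
  stopifnot(inherits(e, "ellipse"))
  uv <- to_ellipse_frame(p, e)
  a <- e$a; b <- e$b
  u <- abs(uv[, 1]); v <- abs(uv[, 2])
  n <- length(u)

  # stationarity of squared distance wrt parametric angle t:
  #   g(t) = (b^2 - a^2) sin t cos t + a u sin t - b v cos t = 0
  starts <- c(1e-8, pi / 6, pi / 3, pi / 2 - 1e-8)
  tbest <- rep(NA_real_, n)
  dbest <- rep(Inf, n)
  d_at <- function(t) sqrt((a * cos(t) - u)^2 + (b * sin(t) - v)^2)
  for (t0 in starts) {
    t <- rep(t0, n)
    for (iter in 1:80) {
      st <- sin(t); ct <- cos(t)
      g <- (b^2 - a^2) * st * ct + a * u * st - b * v * ct
      dg <- (b^2 - a^2) * (ct^2 - st^2) + a * u * ct + b * v * st
      step <- ifelse(dg != 0, g / dg, 0)
      step <- pmax(pmin(step, 0.5), -0.5)   # damp large Newton steps
      t <- pmin(pmax(t - step, 0), pi / 2)
      if (max(abs(step)) < 1e-13) break
    }
    d <- d_at(t)
    upd <- d < dbest
    dbest[upd] <- d[upd]
    tbest[upd] <- t[upd]
  }
  # quadrant vertices are candidates too (boundary of the reduced range)
  for (t in c(0, pi / 2)) {
    d <- d_at(rep(t, n))
    upd <- d < dbest
    dbest[upd] <- d[upd]
    tbest[upd] <- t
  }

  # map the foot point back to the original quadrant and frame
  fu <- a * cos(tbest) * sign(ifelse(uv[, 1] == 0, 1, uv[, 1]))
  fv <- b * sin(tbest) * sign(ifelse(uv[, 2] == 0, 1, uv[, 2]))
  ct <- cos(e$theta); st <- sin(e$theta)
  foot <- cbind(x = e$cx + fu * ct - fv * st,
                y = e$cy + fu * st + fv * ct)
  list(distance = dbest, foot = foot, t = tbest)
}

#' Orthogonal distance from points to an ellipse
#'
#' Shortest Euclidean distance from each point to the ellipse boundary
#' (interior points return their positive distance to the boundary).
#'
#' @inheritParams ellipse_project
#' @return Numeric vector of distances, `>= 0`.
#' @examples
#' e <- ellipse(0, 0, 2, 2)
#' orthogonal_distance(c(3, 0), e)  # 1
#' @export
orthogonal_distance <- function(p, e) {
  ellipse_project(p, e)$distance
}

#' Root mean square orthogonal distance of a point set to an ellipse
#'
#' The RMSE of a fit: the square root of the mean squared orthogonal
#' distance of the points to the ellipse boundary.  Zero exactly when all
#' points lie on the boundary.
#'
#' @inheritParams ellipse_project
#' @return Scalar RMSE, `>= 0`.
#' @export
rmse_ellipse <- function(p, e) {
  sqrt(mean(orthogonal_distance(p, e)^2))
}
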