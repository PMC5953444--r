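# ---- internal linear-algebra helpers ---------------------------------------

# Design matrix of the conic monomials (x^2, xy, y^2, x, y, 1).
conic_design <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  cbind(x^2, x * y, y^2, x, y, 1)
}

# Hartley-style conditioning: centroid shift plus isotropic scaling to
# RMS radius sqrt(2).  Returns the normalized coordinates and the
# transform needed to map a conic fitted in normalized coordinates back.
normalize_xy <- function(xy) {
  mx <- mean(xy[, 1]); my <- mean(xy[, 2])
  dx <- xy[, 1] - mx; dy <- xy[, 2] - my
  s <- sqrt(mean(dx^2 + dy^2) / 2)
  if (s == 0) s <- 1   # all points coincident; caught later as degenerate
  list(xy = cbind(dx / s, dy / s), mx = mx, my = my, s = s)
}

# Map conic coefficients fitted on u=(x-mx)/s, v=(y-my)/s back to (x, y).
denormalize_conic <- function(v, nrm) {
  A <- v[1]; B <- v[2]; C <- v[3]; D <- v[4]; E <- v[5]; F <- v[6]
  mx <- nrm$mx; my <- nrm$my; s <- nrm$s
  out <- c(
    A / s^2,
    B / s^2,
    C / s^2,
    -(2 * A * mx + B * my) / s^2 + D / s,
    -(B * mx + 2 * C * my) / s^2 + E / s,
    (A * mx^2 + B * mx * my + C * my^2) / s^2 - (D * mx + E * my) / s + F
  )
  out / sqrt(sum(out[1:3]^2))   # fix an arbitrary overall scale
}

# Minimize a' S a subject to a' K a = 1 for symmetric PSD K (possibly
# singular).  Components of a in the null space of K are eliminated
# analytically; the reduced problem is an ordinary symmetric eigenproblem.
gen_eig_min <- function(S, K, tol = 1e-10) {
  ek <- eigen(K, symmetric = TRUE)
  pos <- ek$values > tol * max(ek$values)
  V1 <- ek$vectors[, pos, drop = FALSE]
  V0 <- ek$vectors[, !pos, drop = FALSE]
  if (ncol(V0) > 0L) {
    S00 <- crossprod(V0, S %*% V0)
    S01 <- crossprod(V0, S %*% V1)
    Ct <- -solve(S00, S01)            # c = Ct b
    St <- crossprod(V1, S %*% V1) + crossprod(S01, Ct)
  } else {
    St <- crossprod(V1, S %*% V1)
    Ct <- NULL
  }
  li <- 1 / sqrt(ek$values[pos])
  W <- St * tcrossprod(li)            # Lambda^{-1/2} St Lambda^{-1/2}
  ew <- eigen((W + t(W)) / 2, symmetric = TRUE)
  wmin <- ew$vectors[, which.min(ew$values)]
  b <- li * wmin
  a <- V1 %*% b
  if (!is.null(Ct) && ncol(V0) > 0L) a <- a + V0 %*% (Ct %*% b)
  drop(a)
}

# ---- the five fitting algorithms (normalized coordinates in, conic out) ----

# Basic algebraic least squares with the quadratic-coefficient
# normalization A^2 + B^2/2 + C^2 = 1 (invariant under rotation).
solve_algebraic <- function(xy) {
  Dm <- conic_design(xy)
  S <- crossprod(Dm)
  K <- diag(c(1, 0.5, 1, 0, 0, 0))
  list(a = gen_eig_min(S, K), iterations = NA_integer_)
}

# Direct ellipse-specific least squares: minimize ||D a||^2 subject to
# the ellipse constraint 4AC - B^2 = 1, solved as a generalized
# eigenproblem on the full 6x6 system.
solve_direct <- function(xy) {
  Dm <- conic_design(xy)
  S <- crossprod(Dm)
  Cm <- matrix(0, 6, 6)
  Cm[1, 3] <- 2; Cm[3, 1] <- 2; Cm[2, 2] <- -1
  # a tiny ridge keeps the solve well-posed when the data are exact
  ridge <- 1e-12 * mean(diag(S))
  ev <- eigen(solve(S + ridge * diag(6), Cm))
  best <- NULL; best_cost <- Inf
  for (j in seq_len(6)) {
    if (abs(Im(ev$values[j])) > 1e-8 * max(abs(ev$values))) next
    a <- Re(ev$vectors[, j])
    q <- drop(t(a) %*% Cm %*% a)      # = 4AC - B^2 up to scale
    if (q <= 0) next
    a <- a / sqrt(q)
    cost <- drop(t(a) %*% S %*% a)
    if (cost < best_cost) { best <- a; best_cost <- cost }
  }
  if (is.null(best)) stop("direct fit found no ellipse solution")
  list(a = best, iterations = NA_integer_)
}

# Numerically stable block decomposition of the direct method: the
# quadratic and linear coefficient blocks are separated and the
# constraint reduced to a 3x3 eigenproblem.
solve_stable_direct <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)   # inv(C1) %*% M
  ev <- eigen(M)
  a1 <- NULL
  for (j in 1:3) {
    if (abs(Im(ev$values[j])) > 1e-8 * max(abs(ev$values), 1)) next
    v <- Re(ev$vectors[, j])
    if (4 * v[1] * v[3] - v[2]^2 > 0) { a1 <- v; break }
  }
  if (is.null(a1)) stop("stable direct fit found no ellipse solution")
  a1 <- a1 / sqrt(4 * a1[1] * a1[3] - a1[2]^2)
  list(a = c(a1, drop(Tm %*% a1)), iterations = NA_integer_)
}

# Gradient-weighted algebraic fit: minimize the algebraic residual
# normalized by the mean squared gradient of the conic over the data
# (a first-order approximation to geometric distance), as a generalized
# eigenproblem taking the eigenvector of smallest non-negative eigenvalue.
solve_gradient_weighted <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  Dm <- conic_design(xy)
  S <- crossprod(Dm)
  Jx <- cbind(2 * x, y, 0, 1, 0, 0)
  Jy <- cbind(0, x, 2 * y, 0, 1, 0)
  Tm <- crossprod(Jx) + crossprod(Jy)
  list(a = gen_eig_min(S, Tm), iterations = NA_integer_)
}

# Sampson residuals and their analytic Jacobian at conic vector a.
sampson_residuals <- function(a, Dm, Jx, Jy, jacobian = FALSE) {
  f <- drop(Dm %*% a)
  g1 <- drop(Jx %*% a)
  g2 <- drop(Jy %*% a)
  gn <- sqrt(g1^2 + g2^2)
  e <- f / gn
  if (!jacobian) return(list(e = e))
  # d e / d a = u/|g| - f (G' g)/|g|^3
  Gg <- Jx * g1 + Jy * g2
  J <- Dm / gn - Gg * (f / gn^3)
  list(e = e, J = J)
}

# Iterative maximum-likelihood-style fit minimizing the summed squared
# Sampson distance with Levenberg-Marquardt damping, initialized at the
# direct fit.  The minimisation is guaranteed to return an ellipse: a
# barrier term kappa / disc(a)^2, with disc the unit-norm discriminant
# 4AC - B^2, diverges at the boundary of the ellipse region and blocks
# the well-known degenerate drift of the unconstrained Sampson minimum on
# noisy partial arcs towards an arbitrarily large, near-line ellipse.
# kappa is a fixed small fraction (1e-4) of the Sampson cost at the
# initializer, so the barrier is negligible for any well-conditioned
# ellipse (disc of order 0.1-0.4) and vanishes as the data become exact.
# Converges when the relative cost change drops below 1e-12, capped at
# 200 iterations.
solve_sampson <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  Dm <- conic_design(xy)
  Jx <- cbind(2 * x, y, 0, 1, 0, 0)
  Jy <- cbind(0, x, 2 * y, 0, 1, 0)
  a <- tryCatch(solve_direct(xy)$a, error = function(e) solve_stable_direct(xy)$a)
  a <- a / sqrt(sum(a^2))
  disc <- function(a) 4 * a[1] * a[3] - a[2]^2
  kappa <- 1e-4 * sum(sampson_residuals(a, Dm, Jx, Jy)$e^2)
  total <- function(a) sum(sampson_residuals(a, Dm, Jx, Jy)$e^2) +
    kappa / disc(a)^2
  r <- sampson_residuals(a, Dm, Jx, Jy, jacobian = TRUE)
  cost <- total(a)
  lambda <- 1e-6
  iters <- 0L
  converged_flag <- FALSE
  for (it in 1:200) {
    iters <- it
    # Gauss-Newton part from the Sampson residuals plus the analytic
    # gradient/curvature of the barrier in the unit-norm parametrisation.
    JtJ <- crossprod(r$J)
    gvec <- crossprod(r$J, r$e)
    if (kappa > 0) {
      d <- disc(a)
      gd <- c(4 * a[3], -2 * a[2], 4 * a[1], 0, 0, 0)    # grad of disc
      gb <- -2 * kappa / d^3 * gd - 4 * kappa / d^2 * a  # grad of kappa/d^2
                                                         # on the unit sphere
      gvec <- gvec + gb / 2
      JtJ <- JtJ + (6 * kappa / d^4) * tcrossprod(gd) / 2
    }
    improved <- FALSE
    for (k in 1:30) {
      step <- tryCatch(solve(JtJ + lambda * diag(diag(JtJ) + 1e-12), -gvec),
                       error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      a_new <- drop(a + step)
      a_new <- a_new / sqrt(sum(a_new^2))
      if (disc(a_new) <= 0) {
        lambda <- lambda * 10   # reject non-ellipse iterate
        next
      }
      cost_new <- total(a_new)
      if (cost_new < cost) {
        rel <- (cost - cost_new) / max(cost, .Machine$double.xmin)
        a <- a_new
        cost <- cost_new
        lambda <- max(lambda / 10, 1e-12)
        r <- sampson_residuals(a, Dm, Jx, Jy, jacobian = TRUE)
        improved <- TRUE
        if (rel < 1e-12) converged_flag <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!improved || converged_flag) { converged_flag <- TRUE; break }
  }
  list(a = a, iterations = iters)
}

# ---- public interface ------------------------------------------------------

#' Supported ellipse-fitting methods
#'
#' The five fitter families available to [fit_ellipse()]:
#' `"algebraic"` (basic conic least squares with a quadratic-coefficient
#' normalization), `"direct"` (ellipse-specific constrained least squares
#' via a generalized eigenproblem), `"stable_direct"` (its numerically
#' stable block decomposition), `"gradient_weighted"` (algebraic residual
#' weighted by its gradient, approximating geometric distance), and
#' `"sampson_mle"` (iterative minimisation of the Sampson distance).
#'
#' @return Character vector of method names.
#' @export
ellipse_fit_methods <- function() {
  c("algebraic", "direct", "stable_direct", "gradient_weighted", "sampson_mle")
}

#' Fit an ellipse to 2D points
#'
#' Fits the general conic `A x^2 + B x y + C y^2 + D x + E y + F = 0` to a
#' point set using one of five classical algorithms (see
#' [ellipse_fit_methods()]) and converts the result to geometric
#' parameters.  Points are conditioned internally (centroid shift,
#' isotropic scaling to RMS radius `sqrt(2)`) and the conic mapped back
#' afterwards, which makes every method equivariant under translation,
#' rotation and scaling of the data.
#'
#' Methods without an ellipse-specific constraint (`"algebraic"`,
#' `"gradient_weighted"`) can return a non-ellipse conic on noisy data; in
#' that case the fit is flagged `converged = FALSE` and carries no
#' geometric parameters rather than being projected onto an ellipse.
#'
#' With `augment = TRUE` the point set is first passed through the
#' eccentricity-weighted augmentation pre-processor
#' ([preprocess_points()]) and the fit is performed on the augmented set;
#' residual methods still refer to the original points.
#'
#' @param x,y Point coordinates: `x` may be an `n x 2` matrix or a data
#'   frame with columns `x` and `y` (then `y` is omitted), or a numeric
#'   vector paired with `y`.
#' @param method One of [ellipse_fit_methods()].
#' @param augment Logical; pre-process the points with the
#'   eccentricity-weighted augmentation before fitting.
#' @param axis An `"ellipse"` giving the axes used to weight points when
#'   `augment = TRUE`, or `NULL` to estimate them from the data (see
#'   [estimate_axes()]).
#' @param axis_strategy Axis-estimation strategy passed to
#'   [estimate_axes()] when `axis` is `NULL`.
#' @return An object of class `"ellipse_fit"` with components `ellipse`
#'   (an `"ellipse"` or `NULL` if the method failed to produce one),
#'   `conic`, `method`, `converged`, `iterations`, `data` (the original
#'   points) and, when augmentation was requested, `augmented` (the
#'   augmented point set used for the fit).
#' @examples
#' e0 <- ellipse(1, -2, a = 3, b = 1, theta = 0.4)
#' t <- seq(0, 2 * pi, length.out = 13)[-13]
#' pts <- boundary_points(e0, t)
#' fit <- fit_ellipse(pts, method = "direct")
#' coef(fit)
#' @export
fit_ellipse <- function(x, y = NULL,
                        method = c("direct", "stable_direct", "algebraic",
                                   "gradient_weighted", "sampson_mle"),
                        augment = FALSE, axis = NULL,
                        axis_strategy = "ensemble_mean") {
  method <- match.arg(method)
  xy <- if (is.null(y)) as_xy(x) else as_xy(cbind(x, y))
  cl <- match.call()

  if (nrow(xy) < 6L)
    stop("at least 6 points are required to fit a conic")
  ctr <- sweep(xy, 2, colMeans(xy))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[2] < 1e-10 * max(sv[1], 1e-300))
    stop("degenerate input: points are (nearly) collinear")

  aug <- NULL
  fit_xy <- xy
  if (isTRUE(augment)) {
    aug <- preprocess_points(xy, axis = axis, axis_strategy = axis_strategy,
                             method = method)
    fit_xy <- as_xy(aug$points)
  }

  nrm <- normalize_xy(fit_xy)
  solver <- switch(method,
    algebraic = solve_algebraic,
    direct = solve_direct,
    stable_direct = solve_stable_direct,
    gradient_weighted = solve_gradient_weighted,
    sampson_mle = solve_sampson)

  res <- tryCatch(solver(nrm$xy), error = function(e) e)
  if (inherits(res, "error")) {
    out <- structure(list(ellipse = NULL, conic = NULL, method = method,
                          converged = FALSE, iterations = NA_integer_,
                          message = conditionMessage(res), data = xy,
                          augmented = aug, call = cl),
                     class = "ellipse_fit")
    return(out)
  }

  v <- denormalize_conic(res$a, nrm)
  cn <- conic(v[1], v[2], v[3], v[4], v[5], v[6])
  ell <- NULL
  ok <- is_ellipse(cn)
  if (ok) ell <- tryCatch(as_ellipse(cn), error = function(e) NULL)
  structure(list(ellipse = ell, conic = cn, method = method,
                 converged = ok && !is.null(ell),
                 iterations = res$iterations,
                 message = if (ok && !is.null(ell)) NULL
                           else "fit did not produce a real ellipse",
                 data = xy, augmented = aug, call = cl),
            class = "ellipse_fit")
}
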