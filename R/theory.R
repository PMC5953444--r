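#' Construct a theory scenario
#'
#' The idealized setting used to analyse when a supplementary point
#' improves a fit: an axis-aligned, origin-centred ground-truth ellipse
#' with semi-axes `(a0, b0)`, together with `N` noisy first-quadrant
#' samples given in polar coordinates `(r_i, theta_i)`.  The restricted
#' least-squares fit `(a1, b1)` (see [restricted_fit()]) is computed on
#' construction.  By the fourfold reflective symmetrization of the data
#' (see [symmetric_quadruple()]), only the first-quadrant samples need to
#' be carried.
#'
#' @param a0,b0 Ground-truth semi-axes, `a0 >= b0 > 0`.
#' @param r Sample radii, positive.
#' @param theta Sample polar angles in `[0, pi/2]`; both
#'   `sum(cos(theta)^2)` and `sum(sin(theta)^2)` must be positive.
#' @return An object of class `"theory_scenario"` with elements `a0`,
#'   `b0`, `r`, `theta`, `a1`, `b1`, `sc` (`sum cos^2`), `ss`
#'   (`sum sin^2`).
#' @export
theory_scenario <- function(a0, b0, r, theta) {
  stopifnot(a0 > 0, b0 > 0, a0 >= b0, length(r) == length(theta))
  if (any(r <= 0)) stop("radii must be positive")
  if (any(theta < 0 | theta > pi / 2))
    stop("sample angles must lie in [0, pi/2]")
  fit <- restricted_fit(r, theta)
  structure(list(a0 = a0, b0 = b0, r = r, theta = theta,
                 a1 = fit[["a1"]], b1 = fit[["b1"]],
                 sc = sum(cos(theta)^2), ss = sum(sin(theta)^2)),
            class = "theory_scenario")
}

#' @export
print.theory_scenario <- function(x, digits = 6, ...) {
  cat("Theory scenario: truth (a0, b0) = (",
      format(x$a0, digits = digits), ", ", format(x$b0, digits = digits),
      "), N = ", length(x$r), " samples, restricted fit (a1, b1) = (",
      format(x$a1, digits = digits), ", ", format(x$b1, digits = digits),
      ")\n", sep = "")
  invisible(x)
}

#' Restricted least-squares fit of an axis-aligned, origin-centred ellipse
#'
#' Minimizes the mean squared radial-component error
#' `sum((a - r_i)^2 cos^2(theta_i) + (b - r_i)^2 sin^2(theta_i)) / N`
#' over the semi-axes, which decouples into the closed forms
#' `a1 = sum(r cos^2) / sum(cos^2)` and `b1 = sum(r sin^2) / sum(sin^2)`.
#'
#' @param r Sample radii.
#' @param theta Sample polar angles in `[0, pi/2]`.
#' @return Named vector `c(a1, b1)`.
#' @examples
#' restricted_fit(c(2, 1), c(0, pi / 2))  # decoupled: (2, 1)
#' @export
restricted_fit <- function(r, theta) {
  sc <- sum(cos(theta)^2)
  ss <- sum(sin(theta)^2)
  if (sc <= 0 || ss <= 0)
    stop("degenerate fit: samples must span both axes")
  c(a1 = sum(r * cos(theta)^2) / sc,
    b1 = sum(r * sin(theta)^2) / ss)
}

#' L2 approximation error between two axis-aligned ellipses
#'
#' The squared L2 norm of the parametric difference between the ellipse
#' with semi-axes `(a0, b0)` and the one with `(a, b)`, integrated over
#' the full parametric angle: `pi * ((a0 - a)^2 + (b0 - b)^2)`.
#'
#' @param a0,b0 Reference semi-axes.
#' @param a,b Comparison semi-axes.
#' @return Non-negative error value.
#' @export
l2_error <- function(a0, b0, a, b) {
  stopifnot(a0 > 0, b0 > 0, a > 0, b > 0)
  pi * ((a0 - a)^2 + (b0 - b)^2)
}

#' Effect of a supplementary on-axis point
#'
#' Adds a single point at radius `R` on the major axis (with its mirror
#' image, preserving symmetry) to the restricted fit and reports the
#' updated axes and the error improvement.  The updated major semi-axis
#' is `a2 = a1 * beta` with
#' `beta = (sum(cos^2) + R / a1) / (sum(cos^2) + 1)`; the minor axis is
#' unchanged.  The improvement is the closed form
#' `dSigma = pi * (beta - 1) * a1 * (2 a0 - (beta + 1) a1)`, identical to
#' the direct difference of the L2 errors before and after.
#'
#' @param sc A `"theory_scenario"`.
#' @param R Radial position of the supplementary point, `> 0`.
#' @return Named list with `a2`, `b2`, `beta`, `dSigma`.
#' @export
on_axis_update <- function(sc, R) {
  stopifnot(inherits(sc, "theory_scenario"), R > 0)
  beta <- (sc$sc + R / sc$a1) / (sc$sc + 1)
  a2 <- sc$a1 * beta
  dSigma <- pi * (beta - 1) * sc$a1 * (2 * sc$a0 - (beta + 1) * sc$a1)
  list(a2 = a2, b2 = sc$b1, beta = beta, dSigma = dSigma)
}

#' Interval of improving on-axis supplementary radii
#'
#' The supplementary radius improves the fit (`dSigma > 0`) exactly when
#' `R` lies strictly between `a1` and `a1 + da0`, where
#' `da0 = 2 (a0 - a1) (sum(cos^2) + 1)`.  When the restricted fit is
#' unbiased (`a1 = a0`) the interval is empty and no placement improves.
#'
#' @param sc A `"theory_scenario"`.
#' @return Named vector `c(lo, hi)`.
#' @export
on_axis_interval <- function(sc) {
  stopifnot(inherits(sc, "theory_scenario"))
  da0 <- 2 * (sc$a0 - sc$a1) * (sc$sc + 1)
  c(lo = min(sc$a1, sc$a1 + da0), hi = max(sc$a1, sc$a1 + da0))
}

#' Effect of a supplementary off-axis point
#'
#' Adds a single point at polar position `(R, alpha)` in the first
#' quadrant (plus its three reflections) to the restricted fit.  Both
#' axes update multiplicatively, `a2 = a1 * beta` and `b2 = b1 * delta`,
#' with
#' `beta = (sum(cos^2) + (R / a1) cos^2(alpha)) / (sum(cos^2) + cos^2(alpha))`
#' and the analogous `delta` for the minor axis.  The improvement
#' `dSigma` is the sum of the major- and minor-axis terms; at `alpha = 0`
#' it reduces exactly to [on_axis_update()].
#'
#' @param sc A `"theory_scenario"`.
#' @param R Radial position, `> 0`.
#' @param alpha Polar angle of the supplementary point, in `[0, pi/2]`.
#' @return Named list with `a2`, `b2`, `beta`, `delta`, `dSigma`.
#' @export
off_axis_update <- function(sc, R, alpha) {
  stopifnot(inherits(sc, "theory_scenario"), R > 0,
            alpha >= 0, alpha <= pi / 2)
  ca <- cos(alpha)^2; sa <- sin(alpha)^2
  beta <- (sc$sc + (R / sc$a1) * ca) / (sc$sc + ca)
  delta <- (sc$ss + (R / sc$b1) * sa) / (sc$ss + sa)
  a2 <- sc$a1 * beta
  b2 <- sc$b1 * delta
  dSigma <- pi * ((beta - 1) * sc$a1 * (2 * sc$a0 - (beta + 1) * sc$a1) +
                  (delta - 1) * sc$b1 * (2 * sc$b0 - (delta + 1) * sc$b1))
  list(a2 = a2, b2 = b2, beta = beta, delta = delta, dSigma = dSigma)
}

#' Improvement conditions for an off-axis supplementary point
#'
#' Evaluates the two generalized placement intervals governing the sign
#' of the off-axis improvement: the major-axis term of `dSigma` is
#' positive exactly when `R` lies strictly between `a1` and
#' `a1 + da_alpha`, with
#' `da_alpha = 2 (a0 - a1) (sum(cos^2) + cos^2(alpha)) / cos^2(alpha)`,
#' and the minor-axis term exactly when `R` lies strictly between `b1`
#' and `b1 + db_alpha` (analogously with sines).  When each term with a
#' nonzero trigonometric factor lies in its interval — and at least one
#' factor is active — the total improvement is guaranteed positive; this
#' is the condition reported as `satisfied`.  At `alpha = 0` the
#' minor-axis factor vanishes and the condition collapses to the on-axis
#' interval of [on_axis_interval()]; at `alpha = pi/2` only the
#' minor-axis interval remains.
#'
#' @param sc A `"theory_scenario"`.
#' @param R Radial position, `> 0`.
#' @param alpha Polar angle in `[0, pi/2]`.
#' @return A list with `da_alpha`, `db_alpha`, the two intervals
#'   (`a_interval`, `b_interval`), per-term positivity flags
#'   (`in_a_interval`, `in_b_interval`), which branch is active
#'   (`branch`: `"both"`, `"a_only"`, `"b_only"` or `"none"`), and
#'   `satisfied` (placement guarantees `dSigma > 0`).
#' @export
off_axis_conditions <- function(sc, R, alpha) {
  stopifnot(inherits(sc, "theory_scenario"), R > 0,
            alpha >= 0, alpha <= pi / 2)
  ca <- cos(alpha)^2; sa <- sin(alpha)^2
  da <- if (ca > 0) 2 * (sc$a0 - sc$a1) * (sc$sc + ca) / ca else NA_real_
  db <- if (sa > 0) 2 * (sc$b0 - sc$b1) * (sc$ss + sa) / sa else NA_real_
  a_int <- if (ca > 0) sort(c(sc$a1, sc$a1 + da)) else c(NA_real_, NA_real_)
  b_int <- if (sa > 0) sort(c(sc$b1, sc$b1 + db)) else c(NA_real_, NA_real_)
  in_a <- ca > 0 && !anyNA(a_int) && R > a_int[1] && R < a_int[2]
  in_b <- sa > 0 && !anyNA(b_int) && R > b_int[1] && R < b_int[2]
  branch <- if (ca > 0 && sa > 0) {
    if (in_a && in_b) "both" else "none"
  } else if (ca > 0) {
    if (in_a) "a_only" else "none"
  } else {
    if (in_b) "b_only" else "none"
  }
  satisfied <- branch != "none"
  list(da_alpha = da, db_alpha = db,
       a_interval = c(lo = a_int[1], hi = a_int[2]),
       b_interval = c(lo = b_int[1], hi = b_int[2]),
       in_a_interval = in_a, in_b_interval = in_b,
       branch = branch, satisfied = satisfied)
}

#' Classify the sample distribution of a scenario
#'
#' Compares the signed radial residuals `r_i - r_E0(theta_i)` (distance
#' of each sample from the ground-truth boundary along its ray) in the
#' low-angle half (`theta < pi/4`, near the major axis) and the
#' high-angle half, by majority vote of the residual signs:
#' Type 1 — samples predominantly inside the ellipse in both halves;
#' Type 2 — predominantly outside in both;
#' Type 3 — outside near the major axis, inside near the minor axis;
#' Type 4 — the reverse.
#'
#' @param sc A `"theory_scenario"` with samples spanning both halves.
#' @return Integer 1, 2, 3 or 4.
#' @export
classify_scenario <- function(sc) {
  stopifnot(inherits(sc, "theory_scenario"))
  r0 <- sc$a0 * sc$b0 /
    sqrt((sc$b0 * cos(sc$theta))^2 + (sc$a0 * sin(sc$theta))^2)
  res <- sc$r - r0
  if (all(res == 0)) stop("samples lie exactly on the ellipse")
  low <- sc$theta < pi / 4
  if (!any(low) || all(low))
    stop("samples must span both ends of (0, pi/2)")
  sgn <- function(v) sign(sum(sign(v)))
  s_low <- sgn(res[low]); s_high <- sgn(res[!low])
  if (s_low <= 0 && s_high <= 0) return(1L)
  if (s_low >= 0 && s_high >= 0) return(2L)
  if (s_low > 0 && s_high < 0) return(3L)
  4L
}

#' Improvement curves over a grid of supplementary placements
#'
#' Tabulates [off_axis_update()] over a grid of radii for each angle,
#' giving the improvement `dSigma` as a function of `R` and `alpha`
#' (one curve per angle).
#'
#' @param sc A `"theory_scenario"`.
#' @param alpha Vector of angles in `[0, pi/2]`.
#' @param R Vector of radii, `> 0`.
#' @return Data frame with columns `alpha`, `R`, `beta`, `delta`,
#'   `dSigma`.
#' @export
delta_curve <- function(sc, alpha, R) {
  stopifnot(inherits(sc, "theory_scenario"))
  grid <- expand.grid(R = R, alpha = alpha)
  rows <- mapply(function(r, al) {
    u <- off_axis_update(sc, r, al)
    c(u$beta, u$delta, u$dSigma)
  }, grid$R, grid$alpha)
  data.frame(alpha = grid$alpha, R = grid$R,
             beta = rows[1, ], delta = rows[2, ], dSigma = rows[3, ])
}
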