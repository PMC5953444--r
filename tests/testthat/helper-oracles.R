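# Independent oracles used across the test suite.  Each one computes its
# quantity by a route different from the package implementation it checks.

# Random non-degenerate test ellipse.
random_ellipse <- function(max_ecc = 0.99) {
  a <- runif(1, 0.5, 10)
  b <- a * sqrt(1 - runif(1, 0, max_ecc)^2)
  ellipse(runif(1, -5, 5), runif(1, -5, 5), a, b, runif(1, 0, pi))
}

# Brute-force nearest-distance oracle: dense parametric sampling.
dense_distance <- function(p, e, n = 2e5) {
  bp <- boundary_points(e, seq(0, 2 * pi, length.out = n))
  min(sqrt((bp[, 1] - p[1])^2 + (bp[, 2] - p[2])^2))
}

# Quadrature oracle for the sector mean point eccentricity of an
# axis-aligned ellipse under uniform parametric-angle sampling.
quadrature_mean_xi <- function(a, b, spec) {
  eps <- sqrt(a^2 - b^2) / a
  xi <- function(t) eps * abs(a * cos(t)) / (abs(a * cos(t)) + abs(b * sin(t)))
  tot <- 0
  len <- 0
  for (r in seq_len(nrow(spec))) {
    tot <- tot + integrate(xi, spec[r, 1], spec[r, 2],
                           subdivisions = 2000L, rel.tol = 1e-10)$value
    len <- len + spec[r, 2] - spec[r, 1]
  }
  unname(tot / len)
}

# Independent step-by-step systematic-resampling simulation: number of
# traversal steps of size 1/Tn landing in each cumulative-weight bin.
systematic_counts <- function(W, Tn) {
  cw <- cumsum(W)
  cw[length(cw)] <- 1
  counts <- integer(length(W))
  for (t in seq_len(Tn)) {
    mu <- t / Tn
    s <- which(mu <= cw + 1e-12)[1]
    counts[s] <- counts[s] + 1L
  }
  counts
}

# Reference conic fit by direct numeric optimisation: minimises the sum
# of squared algebraic residuals over the geometric parameters with the
# conic scaled to 4AC - B^2 = 1 (the ellipse-specific least-squares
# objective), using general-purpose optimisers.  Independent of the
# package's eigen-decomposition route.
optim_direct_fit <- function(p, start) {
  xy <- p
  cost <- function(th) {
    e <- tryCatch(ellipse(th[1], th[2], exp(th[3]), exp(th[4]), th[5]),
                  error = function(err) NULL)
    if (is.null(e)) return(1e12)
    v <- as.numeric(as_conic(e))   # normalized so B^2 - 4AC = -1
    sum((v[1] * xy[, 1]^2 + v[2] * xy[, 1] * xy[, 2] + v[3] * xy[, 2]^2 +
           v[4] * xy[, 1] + v[5] * xy[, 2] + v[6])^2)
  }
  th0 <- c(start$cx, start$cy, log(start$a), log(start$b), start$theta)
  o <- optim(th0, cost, method = "Nelder-Mead",
             control = list(maxit = 5000, reltol = 1e-14))
  o <- optim(o$par, cost, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-14))
  ellipse(o$par[1], o$par[2], exp(o$par[3]), exp(o$par[4]), o$par[5])
}

# Numeric minimiser of the restricted mean-square radial error over
# (a, b), independent of the closed forms.
optim_restricted_fit <- function(r, theta) {
  cost <- function(ab) mean((ab[1] - r)^2 * cos(theta)^2 +
                              (ab[2] - r)^2 * sin(theta)^2)
  o <- optim(c(mean(r), mean(r)), cost, method = "Nelder-Mead",
             control = list(reltol = 1e-15, maxit = 10000))
  optim(o$par, cost, method = "BFGS",
        control = list(reltol = 1e-15, maxit = 1000))$par
}

# Random theory scenario: noisy polar samples of a ground-truth ellipse
# in the first quadrant, spanning both halves of (0, pi/2).  `bias`
# scales all radii, moving the sample cloud inside (< 1) or outside
# (> 1) the true boundary.
random_scenario <- function(n = 20, a0 = NULL, b0 = NULL, rel_noise = 0.1,
                            bias = 1) {
  if (is.null(a0)) a0 <- runif(1, 1, 10)
  if (is.null(b0)) b0 <- a0 * runif(1, 0.2, 1)
  th <- sort(runif(n, 0, pi / 2))
  th[1] <- runif(1, 0, pi / 8); th[n] <- runif(1, 3 * pi / 8, pi / 2)
  r0 <- a0 * b0 / sqrt((b0 * cos(th))^2 + (a0 * sin(th))^2)
  r <- bias * r0 * (1 + runif(n, -rel_noise, rel_noise))
  theory_scenario(a0, b0, r, th)
}
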