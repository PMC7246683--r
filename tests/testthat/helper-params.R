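# Canonical parameter sets used across the suite (the published simulation
# settings) and small numeric helpers.

params_s51 <- function(...) {
  p <- unclass(scenario_config("s51")$params)
  validate_params(utils::modifyList(p, list(...)))
}

params_s52 <- function(...) {
  p <- unclass(scenario_config("s52")$params)
  validate_params(utils::modifyList(p, list(...)))
}

params_s53 <- function(...) {
  p <- unclass(scenario_config("s53")$params)
  validate_params(utils::modifyList(p, list(...)))
}

# central finite-difference Jacobian, the oracle for the analytic one
fd_jacobian <- function(f, x, h_rel = 1e-6) {
  n <- length(x)
  fx <- f(x)
  J <- matrix(0, length(fx), n)
  for (j in seq_len(n)) {
    h <- h_rel * max(abs(x[j]), 1)
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# integrate the 2D demand system and return the terminal state (oracle for
# basin assignment)
terminal_2d <- function(y0, params, t_end = 500) {
  rhs <- function(t, y, parms) list(unname(rhs_2d(y, params)))
  sol <- deSolve::lsoda(stats::setNames(y0, c("N1", "N2")), c(0, t_end),
                        rhs, NULL, rtol = 1e-10, atol = 1e-10)
  sol[nrow(sol), 2:3]
}

rhs_norm <- function(v) sqrt(sum(v^2))

# distance from a point to a polyline (segment-wise)
point_dist_to_curve <- function(pt, curve) {
  x <- curve$N1; y <- curve$N2
  dx <- diff(x); dy <- diff(y)
  len2 <- pmax(dx^2 + dy^2, .Machine$double.eps)
  t <- ((pt[1] - x[-length(x)]) * dx + (pt[2] - y[-length(y)]) * dy) / len2
  t <- pmin(pmax(t, 0), 1)
  min(sqrt((pt[1] - (x[-length(x)] + t * dx))^2 +
             (pt[2] - (y[-length(y)] + t * dy))^2))
}
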