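#' Simulate the four-dimensional dual-channel system
#'
#' Integrates [rhs_4d()] with an adaptive, stiffness-switching solver
#' ([deSolve::lsoda()]) and returns the trajectory on a uniform output grid.
#' States that leave the admissible region G' by more than a clip tolerance
#' are flagged (never silently clipped); drift within the tolerance (the
#' usual tiny negative overshoot of a component decaying to zero) is
#' clipped back onto the region.
#'
#' @param params an [model_params()] object.
#' @param state0 named numeric `c(N1, I1, N2, I2)` in G'.
#' @param t_end positive horizon (abstract time units, as in the model).
#' @param grid number of output points (default 1000).
#' @param rtol,atol solver tolerances.
#' @param clip_tol relative tolerance (scaled by `max(K1,K2)`) within which
#'   out-of-region drift is clipped; violations beyond it raise a flag.
#' @return An object of class `sis_trajectory`: a data frame with columns
#'   `time`, `N1`, `I1`, `N2`, `I2` plus attributes `params`, `flags` and
#'   `solver` (tolerances and diagnostics).
#' @examples
#' p <- model_params(1, 1, 1000, 1000, -1.2, -1.5,
#'                   beta11 = 9e-05, beta12 = 0.05, beta21 = 0.05,
#'                   beta22 = 0.05, gamma1 = 0.01, gamma2 = 0.01)
#' traj <- simulate_sis(p, c(N1 = 100, I1 = 1, N2 = 100, I2 = 1), t_end = 50,
#'                      grid = 101)
#' utils::tail(total_sales_series(traj))
#' @export
simulate_sis <- function(params, state0, t_end, grid = 1000,
                         rtol = 1e-9, atol = 1e-12, clip_tol = 1e-6) {
  p <- validate_params(params)
  if (t_end <= 0) stop("'t_end' must be positive", call. = FALSE)
  if (length(state0) != 4L) {
    stop("'state0' must have four components (N1, I1, N2, I2)",
         call. = FALSE)
  }
  state0 <- stats::setNames(as.numeric(state0), c("N1", "I1", "N2", "I2"))
  if (!in_region(state0, p, tol = 1e-9)) {
    stop("'state0' lies outside the admissible region G'", call. = FALSE)
  }
  cpl <- if (p$demographic_coupling) 1 else 0
  deriv <- function(t, y, parms) {
    g1 <- p$r1 * (1 - y[1] / p$K1) + p$m * y[3] / p$K2
    g2 <- p$r2 * (1 - y[3] / p$K2) + p$n * y[1] / p$K1
    list(c(y[1] * g1,
           (p$beta11 * y[2] + p$beta12 * y[4]) * (y[1] - y[2]) -
             p$gamma1 * y[2] + cpl * g1 * y[2],
           y[3] * g2,
           (p$beta21 * y[2] + p$beta22 * y[4]) * (y[3] - y[4]) -
             p$gamma2 * y[4] + cpl * g2 * y[4]))
  }
  times <- seq(0, t_end, length.out = max(2L, as.integer(grid)))
  sol <- deSolve::lsoda(state0, times, deriv, NULL, rtol = rtol, atol = atol,
                        maxsteps = 100000)
  if (attr(sol, "istate")[1] < 0) {
    stop("integration failed; last valid state: ",
         paste(signif(sol[nrow(sol), -1], 6), collapse = ", "),
         call. = FALSE)
  }
  out <- as.data.frame(unclass(sol))
  names(out)[1] <- "time"
  flags <- character(0)
  eps <- clip_tol * max(p$K1, p$K2, 1)
  lower_viol <- min(out$N1, out$I1, out$N2, out$I2)
  cap_viol <- max(out$N1 - p$K1, out$N2 - p$K2,
                  out$I1 - out$N1, out$I2 - out$N2)
  if (lower_viol < -eps || cap_viol > eps) {
    flags <- c(flags, sprintf(
      "trajectory left G' beyond tolerance (min coord %.3g, max excess %.3g)",
      lower_viol, cap_viol))
  } else {
    for (v in c("N1", "I1", "N2", "I2")) out[[v]] <- pmax(out[[v]], 0)
    out$I1 <- pmin(out$I1, out$N1)
    out$I2 <- pmin(out$I2, out$N2)
  }
  structure(out, params = p, flags = flags,
            solver = list(method = "lsoda", rtol = rtol, atol = atol,
                          steps = unname(attr(sol, "istate")[2])),
            class = c("sis_trajectory", "data.frame"))
}

#' Total-sales time series of a trajectory
#'
#' The model's headline output: combined purchasers `I1 + I2` over time.
#'
#' @param traj an `sis_trajectory` from [simulate_sis()].
#' @return A data frame with columns `time` and `total_sales` (persons).
#' @export
total_sales_series <- function(traj) {
  stopifnot(inherits(traj, "sis_trajectory"))
  data.frame(time = traj$time, total_sales = traj$I1 + traj$I2)
}

#' Detect convergence of a trajectory to a known equilibrium
#'
#' Matches the trajectory's tail (the last 10% of the horizon, every output
#' point) against candidate equilibria; a candidate matches when the whole
#' tail stays within `tol` (relative to the coordinate scale) of its
#' coordinates.
#'
#' @param traj an `sis_trajectory`.
#' @param candidates a list of `sis_equilibrium` objects (e.g. from
#'   [enumerate_equilibria_4d()]); points with `exists = FALSE` are skipped.
#' @param tol relative tolerance (default 1e-3).
#' @return The matched label as a character scalar, or `"none"`.
#' @export
detect_convergence <- function(traj, candidates, tol = 1e-3) {
  stopifnot(inherits(traj, "sis_trajectory"))
  tail_idx <- which(traj$time >= 0.9 * max(traj$time))
  tail_states <- as.matrix(traj[tail_idx, c("N1", "I1", "N2", "I2")])
  for (e in candidates) {
    if (!isTRUE(e$exists) || length(e$coords) != 4L) next
    scale <- max(1, sqrt(sum(e$coords^2)))
    d <- sqrt(rowSums(sweep(tail_states, 2, e$coords)^2))
    if (all(d <= tol * scale)) return(e$label)
  }
  "none"
}

#' Nullclines of the two-dimensional demand system
#'
#' Each demand equation vanishes on a coordinate axis and on one interior
#' straight line: `r1(1 - N1/K1) + m N2/K2 = 0` for channel 1 and
#' `r2(1 - N2/K2) + n N1/K1 = 0` for channel 2. The intersection of the
#' interior lines, when it lies in G, is the demand equilibrium M.
#'
#' @param params an [model_params()] object.
#' @param grid number of points per curve (>= 2).
#' @return A list with data frames `N1_null` and `N2_null` (columns `N1`,
#'   `N2`, `branch` in `{"axis", "interior"}`) and `intersection` (the
#'   interior intersection point, `NA` when the lines are parallel).
#' @export
nullclines_2d <- function(params, grid = 201) {
  p <- validate_params(params)
  grid <- max(2L, as.integer(grid))
  n1 <- seq(0, p$K1, length.out = grid)
  n2 <- seq(0, p$K2, length.out = grid)
  # dN1/dt = 0: N1 = 0 or r1(1 - N1/K1) + m N2/K2 = 0
  int1 <- if (p$m != 0) {
    data.frame(N1 = n1, N2 = p$K2 / p$m * (p$r1 * n1 / p$K1 - p$r1),
               branch = "interior")
  } else {
    data.frame(N1 = rep(p$K1, grid), N2 = n2, branch = "interior")
  }
  int2 <- if (p$n != 0) {
    data.frame(N1 = p$K1 / p$n * (p$r2 * n2 / p$K2 - p$r2), N2 = n2,
               branch = "interior")
  } else {
    data.frame(N1 = n1, N2 = rep(p$K2, grid), branch = "interior")
  }
  d <- p$r1 * p$r2 - p$m * p$n
  inter <- if (d == 0) {
    c(N1 = NA_real_, N2 = NA_real_)
  } else {
    c(N1 = (p$m + p$r1) * p$r2 * p$K1 / d,
      N2 = (p$n + p$r2) * p$r1 * p$K2 / d)
  }
  list(
    N1_null = rbind(data.frame(N1 = 0, N2 = n2, branch = "axis"), int1),
    N2_null = rbind(data.frame(N1 = n1, N2 = 0, branch = "axis"), int2),
    intersection = inter
  )
}

#' Separatrix and basin partition of the bistable demand system
#'
#' In the bistable regime the interior demand equilibrium M is a saddle
#' whose stable manifold divides G into the basin of P(K1, 0) and the basin
#' of Q(0, K2). The two manifold branches are traced by integrating the
#' demand system backward in time from `M +/- eps * v_stable`, where
#' `v_stable` is the stable eigendirection of the Jacobian at M, until the
#' trajectory reaches the boundary of G (or an arc-length cap). Membership
#' of a query point is decided by counting crossings of the joined
#' separatrix polyline on the segment from the query point to a reference
#' point deep in the basin of P.
#'
#' @param params an [model_params()] object (bistable regime).
#' @param M optional precomputed demand equilibrium M.
#' @param eps displacement along the stable eigendirection, relative to
#'   `max(K1, K2)`.
#' @param arc_cap arc-length cap per branch, relative to `max(K1, K2)`.
#' @return An object of class `basin_partition`: list with `M` (coords),
#'   `branches` (list of two polyline data frames, each ending at M), and
#'   the region labels. Use [basin_label()] to classify points; region `Y`
#'   is the basin of P(K1, 0) and region `X` the basin of Q(0, K2).
#' @export
separatrix_2d <- function(params, M = NULL, eps = 1e-4, arc_cap = 10) {
  p <- validate_params(params)
  if (is.null(M)) M <- demand_equilibria_2d(p)$M
  if (!isTRUE(M$exists)) stop("M does not exist", call. = FALSE)
  J <- jacobian_2d(M$coords, p)
  ev <- eigen(J)
  re <- Re(ev$values)
  if (!(min(re) < 0 && max(re) > 0)) {
    stop("M is not a saddle of the demand system; the separatrix/basin ",
         "partition is defined in the bistable regime only", call. = FALSE)
  }
  vs <- Re(ev$vectors[, which.min(re)])
  vs <- vs / sqrt(sum(vs^2))
  scale <- max(p$K1, p$K2)
  m0 <- M$coords
  # unit-speed reversed flow: tracing the manifold by arc length avoids the
  # finite-time blowups of the reversed logistic dynamics and yields a
  # uniformly spaced polyline
  fscale <- max(p$r1, p$r2) * scale
  back <- function(dir) {
    y0 <- m0 + dir * eps * scale * vs
    rhs_arc <- function(s, y, parms) {
      g1 <- p$r1 * (1 - y[1] / p$K1) + p$m * y[2] / p$K2
      g2 <- p$r2 * (1 - y[2] / p$K2) + p$n * y[1] / p$K1
      f <- c(y[1] * g1, y[2] * g2)
      list(-f / (sqrt(sum(f^2)) + 1e-12 * fscale))
    }
    speed_at <- function(y) {
      g1 <- p$r1 * (1 - y[1] / p$K1) + p$m * y[2] / p$K2
      g2 <- p$r2 * (1 - y[2] / p$K2) + p$n * y[1] / p$K1
      sqrt((y[1] * g1)^2 + (y[2] * g2)^2)
    }
    pts <- matrix(y0, ncol = 2)
    s_leg <- 0.05 * scale
    pad <- 1e-7 * scale
    for (leg in seq_len(ceiling(arc_cap * scale / s_leg))) {
      # near a demand equilibrium the regularised unit-speed field stalls;
      # lsoda then returns the partial leg, which the speed check below ends
      sol <- suppressWarnings(
        deSolve::lsoda(pts[nrow(pts), ], seq(0, s_leg, length.out = 11),
                       rhs_arc, NULL, rtol = 1e-10, atol = 1e-10 * scale,
                       maxsteps = 20000))
      seg <- unname(sol[-1, 2:3, drop = FALSE])
      outside <- seg[, 1] < -pad | seg[, 2] < -pad |
        seg[, 1] > p$K1 + pad | seg[, 2] > p$K2 + pad
      # a stalling flow speed means the branch has run into a demand
      # equilibrium (e.g. the origin): stop there, before the unit-speed
      # field becomes too stiff to advance
      stalled <- apply(seg, 1, speed_at) < 1e-4 * fscale
      cut <- which(outside | stalled)
      if (length(cut)) {
        pts <- rbind(pts, seg[seq_len(cut[1]), , drop = FALSE])
        break
      }
      pts <- rbind(pts, seg)
    }
    pts[, 1] <- pmin(pmax(pts[, 1], 0), p$K1)
    pts[, 2] <- pmin(pmax(pts[, 2], 0), p$K2)
    data.frame(N1 = rev(pts[, 1]), N2 = rev(pts[, 2]))
  }
  b1 <- back(+1)
  b2 <- back(-1)
  # joined polyline across G, passing through M
  curve <- rbind(b1, data.frame(N1 = m0[["N1"]], N2 = m0[["N2"]]),
                 b2[rev(seq_len(nrow(b2))), ])
  structure(list(M = m0, branches = list(b1, b2), curve = curve,
                 params = p, labels = c(P_basin = "Y", Q_basin = "X")),
            class = "basin_partition")
}

# segment intersection test for the crossing count
segments_cross <- function(a1, a2, b1, b2) {
  d <- function(u, v, w) (v[1] - u[1]) * (w[2] - u[2]) -
    (v[2] - u[2]) * (w[1] - u[1])
  d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
  d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

point_polyline_distance <- function(pt, curve) {
  x <- curve$N1; y <- curve$N2
  dx <- diff(x); dy <- diff(y)
  len2 <- dx^2 + dy^2
  len2[len2 == 0] <- 1
  t <- ((pt[1] - x[-length(x)]) * dx + (pt[2] - y[-length(y)]) * dy) / len2
  t <- pmin(pmax(t, 0), 1)
  px <- x[-length(x)] + t * dx
  py <- y[-length(y)] + t * dy
  min(sqrt((pt[1] - px)^2 + (pt[2] - py)^2))
}

#' Basin membership of a demand state
#'
#' Classifies a point of the demand plane against a [separatrix_2d()]
#' partition: `"Y"` (basin of P(K1,0)), `"X"` (basin of Q(0,K2)) or
#' `"separatrix"` when the point lies within `on_tol` of the curve.
#'
#' @param state numeric `c(N1, N2)`.
#' @param partition a `basin_partition`.
#' @param on_tol on-curve tolerance relative to `max(K1, K2)`.
#' @return `"X"`, `"Y"` or `"separatrix"`.
#' @export
basin_label <- function(state, partition, on_tol = 1e-6) {
  stopifnot(inherits(partition, "basin_partition"))
  p <- partition$params
  scale <- max(p$K1, p$K2)
  pt <- as.numeric(state)[1:2]
  if (point_polyline_distance(pt, partition$curve) <= on_tol * scale) {
    return("separatrix")
  }
  # reference point deep in the basin of P(K1, 0)
  ref <- c(0.999 * p$K1, 1e-4 * p$K2)
  cv <- partition$curve
  n <- nrow(cv)
  crossings <- 0L
  for (i in seq_len(n - 1L)) {
    if (segments_cross(pt, ref, c(cv$N1[i], cv$N2[i]),
                       c(cv$N1[i + 1L], cv$N2[i + 1L]))) {
      crossings <- crossings + 1L
    }
  }
  if (crossings %% 2L == 0L) "Y" else "X"
}

#' Omega-region membership of a four-dimensional state
#'
#' Evaluates the thirteen region predicates used by the condition table:
#' Omega1 is all of G'; the others restrict coordinates to be nonzero
#' (tested against `tol * max(K1, K2)`) and/or confine the demand
#' projection `(N1, N2)` to basin X, basin Y or the separatrix itself.
#'
#' @param state numeric `c(N1, I1, N2, I2)`.
#' @param params an [model_params()] object.
#' @param partition a [separatrix_2d()] partition; required for the
#'   basin-dependent labels (Omega2, 3, 6, 7, 12, 13). Without one those
#'   labels are simply not evaluated, unless `labels` explicitly requests
#'   one, which is then an error.
#' @param tol relative nonzero tolerance.
#' @param labels optional character vector restricting the labels to
#'   evaluate.
#' @return Character vector of all satisfied labels (intersected with
#'   `labels` when given).
#' @export
omega_region_membership <- function(state, params, partition = NULL,
                                    tol = 1e-9, labels = NULL) {
  p <- validate_params(params)
  basin_labels <- c("Omega2", "Omega3", "Omega6", "Omega7",
                    "Omega12", "Omega13")
  if (!is.null(labels) && is.null(partition) &&
      any(labels %in% basin_labels)) {
    stop("labels ", paste(intersect(labels, basin_labels), collapse = ", "),
         " depend on the basin partition; supply 'partition'",
         call. = FALSE)
  }
  if (!in_region(state, p, tol = 1e-6)) return(character(0))
  eps <- tol * max(p$K1, p$K2, 1)
  N1 <- state[[1]]; I1 <- state[[2]]; N2 <- state[[3]]; I2 <- state[[4]]
  nz <- function(x) abs(x) > eps
  labs <- "Omega1"
  if (nz(N1)) labs <- c(labs, "Omega4")
  if (nz(N1) && nz(I1)) labs <- c(labs, "Omega5")
  if (nz(N2)) labs <- c(labs, "Omega8")
  if (nz(N2) && nz(I2)) labs <- c(labs, "Omega9")
  if (nz(N1) && nz(N2)) labs <- c(labs, "Omega10")
  if (nz(N1) && nz(I1) && nz(N2) && nz(I2)) labs <- c(labs, "Omega11")
  if (is.null(partition)) {
    labs <- sort(labs)
    if (!is.null(labels)) labs <- intersect(labels, labs)
    return(labs)
  }
  side <- basin_label(c(N1, N2), partition)
  if (side == "Y") {
    labs <- c(labs, "Omega2")
    if (nz(I1)) labs <- c(labs, "Omega3")
  }
  if (side == "X") {
    labs <- c(labs, "Omega6")
    if (nz(I2)) labs <- c(labs, "Omega7")
  }
  if (side == "separatrix") {
    labs <- c(labs, "Omega12")
    if (nz(I1) && nz(I2)) labs <- c(labs, "Omega13")
  }
  labs <- sort(labs)
  if (!is.null(labels)) labs <- intersect(labels, labs)
  labs
}

#' Write a trajectory to CSV with JSON metadata
#'
#' @param traj an `sis_trajectory`.
#' @param path output CSV path (columns `t, N1, I1, N2, I2, total_sales`);
#'   a `.json` sidecar with parameters and solver settings is written next
#'   to it.
#' @return Invisibly, the CSV path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "sis_trajectory"))
  out <- data.frame(t = traj$time, N1 = traj$N1, I1 = traj$I1,
                    N2 = traj$N2, I2 = traj$I2,
                    total_sales = traj$I1 + traj$I2)
  utils::write.csv(out, path, row.names = FALSE)
  meta <- list(params = unclass(attr(traj, "params")),
               solver = attr(traj, "solver"),
               flags = attr(traj, "flags"))
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
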