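#' Analytic Jacobian of the two-dimensional demand system
#'
#' @param state numeric `c(N1, N2)`.
#' @param params an [model_params()] object.
#' @return A 2x2 numeric matrix of partial derivatives of [rhs_2d()].
#' @export
jacobian_2d <- function(state, params) {
  p <- validate_params(params)
  N1 <- state[[1]]; N2 <- state[[2]]
  g <- growth_terms(N1, N2, p)
  matrix(c(g[["g1"]] - p$r1 * N1 / p$K1,  p$m * N1 / p$K2,
           p$n * N2 / p$K1,               g[["g2"]] - p$r2 * N2 / p$K2),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("dN1", "dN2"), c("N1", "N2")))
}

#' Analytic Jacobian of the four-dimensional system
#'
#' Partial derivatives of [rhs_4d()] in state order `(N1, I1, N2, I2)`.
#' Because the demand equations never depend on the purchase counts, the
#' matrix is block lower-triangular in the (N, I) grouping: its spectrum is
#' the union of the 2x2 demand block and the 2x2 purchase block.
#'
#' @param state numeric `c(N1, I1, N2, I2)`.
#' @param params an [model_params()] object.
#' @return A 4x4 numeric matrix.
#' @export
jacobian_4d <- function(state, params) {
  p <- validate_params(params)
  N1 <- state[[1]]; I1 <- state[[2]]; N2 <- state[[3]]; I2 <- state[[4]]
  g <- growth_terms(N1, N2, p)
  cpl <- if (p$demographic_coupling) 1 else 0
  force1 <- p$beta11 * I1 + p$beta12 * I2
  force2 <- p$beta21 * I1 + p$beta22 * I2
  J <- matrix(0, 4, 4,
              dimnames = list(c("dN1", "dI1", "dN2", "dI2"),
                              c("N1", "I1", "N2", "I2")))
  J["dN1", "N1"] <- g[["g1"]] - p$r1 * N1 / p$K1
  J["dN1", "N2"] <- p$m * N1 / p$K2
  J["dI1", "N1"] <- force1 - cpl * I1 * p$r1 / p$K1
  J["dI1", "I1"] <- p$beta11 * (N1 - I1) - force1 - p$gamma1 +
    cpl * g[["g1"]]
  J["dI1", "N2"] <- cpl * I1 * p$m / p$K2
  J["dI1", "I2"] <- p$beta12 * (N1 - I1)
  J["dN2", "N1"] <- p$n * N2 / p$K1
  J["dN2", "N2"] <- g[["g2"]] - p$r2 * N2 / p$K2
  J["dI2", "N1"] <- cpl * I2 * p$n / p$K1
  J["dI2", "I1"] <- p$beta21 * (N2 - I2)
  J["dI2", "N2"] <- force2 - cpl * I2 * p$r2 / p$K2
  J["dI2", "I2"] <- p$beta22 * (N2 - I2) - force2 - p$gamma2 +
    cpl * g[["g2"]]
  J
}

verdict_from_eigen <- function(ev, tol) {
  re <- Re(ev)
  if (any(abs(re) <= tol)) return("nonhyperbolic")
  if (all(re < 0)) return("asymptotically stable")
  if (all(re > 0)) return("unstable")
  "saddle"
}

#' Eigenvalue stability classification of an equilibrium
#'
#' Computes the eigenvalues of the Jacobian at an equilibrium point and
#' classifies it as asymptotically stable (all real parts negative),
#' unstable (all positive), saddle (both signs) or nonhyperbolic (a real
#' part within `tol` of zero, never silently assigned). For 4D points the
#' purchase-block eigenvalues are also reported separately: when a
#' stability claim is conditional on the demand state lying on the saddle's
#' stable manifold, the purchase block carries the relevant part of the
#' spectrum (the demand motion there converges to M).
#'
#' @param point an `sis_equilibrium` (2D or 4D coordinates) that exists.
#' @param params an [model_params()] object.
#' @param tol nonhyperbolicity threshold; default `1e-8` times the largest
#'   rate scale `max(r1, r2, gamma1, gamma2)`.
#' @return An object of class `stability_report`: list with `label`,
#'   `eigenvalues` (sorted by real part), `verdict`, and for 4D points
#'   `eigenvalues_I` and `verdict_I` for the purchase block.
#' @export
classify_by_eigenvalues <- function(point, params, tol = NULL) {
  p <- validate_params(params)
  if (!isTRUE(point$exists)) {
    stop("cannot classify a nonexistent equilibrium point (",
         point$label, ")", call. = FALSE)
  }
  if (is.null(tol)) tol <- 1e-8 * max(p$r1, p$r2, p$gamma1, p$gamma2)
  co <- point$coords
  out <- list(label = point$label, tol = tol)
  if (length(co) == 2L) {
    ev <- eigen(jacobian_2d(co, p), only.values = TRUE)$values
    out$eigenvalues <- ev[order(Re(ev))]
    out$verdict <- verdict_from_eigen(ev, tol)
  } else {
    J <- jacobian_4d(co, p)
    ev <- eigen(J, only.values = TRUE)$values
    out$eigenvalues <- ev[order(Re(ev))]
    out$verdict <- verdict_from_eigen(ev, tol)
    evI <- eigen(J[c("dI1", "dI2"), c("I1", "I2")], only.values = TRUE)$values
    out$eigenvalues_I <- evI[order(Re(evI))]
    out$verdict_I <- verdict_from_eigen(evI, tol)
  }
  class(out) <- "stability_report"
  out
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("%s: %s\n", x$label, x$verdict))
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 4),
                              collapse = ", "), "\n")
  if (!is.null(x$verdict_I)) {
    cat(sprintf("  purchase block: %s (%s)\n", x$verdict_I,
                paste(format(x$eigenvalues_I, digits = 4), collapse = ", ")))
  }
  invisible(x)
}

#' Condition-table stability classification
#'
#' Evaluates the published condition table row by row: the demand-regime
#' inequalities, the reproduction numbers against one, the signs of
#' `A - beta11*N1E` and `B - beta22*N2E`, and the ordering of the invasion
#' ratios Pi1, Pi2. For the parameter set supplied it returns every row
#' that fires, with the equilibrium point, the implied verdict and the
#' region label (Omega_1 ... Omega_13) on which stability is claimed.
#' Region labels ending in 12/13 confine the demand state to the saddle's
#' stable manifold (the separatrix); labels 2/3 and 6/7 confine it to one
#' basin of attraction.
#'
#' @param params an [model_params()] object.
#' @param tol boundary tolerance; parameter sets within `tol` of any strict
#'   inequality used by a row are reported with `degenerate = TRUE`.
#' @return A data frame with columns `point`, `condition`, `verdict`,
#'   `region`, `degenerate`.
#' @export
classify_by_conditions <- function(params, tol = 1e-12) {
  p <- validate_params(params)
  regime <- classify_regime(p, tol)
  R <- reproduction_numbers(p)
  rows <- list(list(point = "P0", condition = "always",
                    verdict = "unstable", region = "Omega1",
                    degenerate = FALSE))
  deg_R1 <- abs(R[["R1"]] - 1) <= tol
  deg_R2 <- abs(R[["R2"]] - 1) <= tol
  add <- function(point, condition, verdict, region, degenerate = FALSE) {
    rows[[length(rows) + 1L]] <<- list(point = point, condition = condition,
                                       verdict = verdict, region = region,
                                       degenerate = degenerate)
  }
  pi_rows <- function(region_P5, region_P6) {
    th <- interior_thresholds(p)
    if (!th$A_cond || !th$B_cond || length(th$undefined)) return(invisible())
    deg <- is.finite(th$Pi1) && is.finite(th$Pi2) &&
      abs(th$Pi1 - th$Pi2) <= tol
    if (th$Pi1 > th$Pi2) {
      add("P5", "A-b11*N1E>0, B-b22*N2E>0, Pi1>Pi2",
          "asymptotically stable", region_P5, deg)
    } else {
      add("P6", "A-b11*N1E>0, B-b22*N2E>0, Pi1<Pi2",
          "asymptotically stable", region_P6, deg)
    }
  }
  if (regime == "bistable") {
    if (R[["R1"]] < 1) {
      add("P1", "bistable, R1<1", "asymptotically stable", "Omega2", deg_R1)
    } else {
      add("P2", "bistable, R1>1", "asymptotically stable", "Omega3", deg_R1)
    }
    if (R[["R2"]] < 1) {
      add("P3", "bistable, R2<1", "asymptotically stable", "Omega6", deg_R2)
    } else {
      add("P4", "bistable, R2>1", "asymptotically stable", "Omega7", deg_R2)
    }
    pi_rows("Omega12", "Omega13")
  } else if (regime == "coexistence") {
    pi_rows("Omega10", "Omega11")
  } else if (regime == "channel1-dominant") {
    if (R[["R1"]] < 1) {
      add("P1", "channel1-dominant, R1<1", "asymptotically stable",
          "Omega4", deg_R1)
    } else {
      add("P2", "channel1-dominant, R1>1", "asymptotically stable",
          "Omega5", deg_R1)
    }
  } else if (regime == "channel2-dominant") {
    if (R[["R2"]] < 1) {
      add("P3", "channel2-dominant, R2<1", "asymptotically stable",
          "Omega8", deg_R2)
    } else {
      add("P4", "channel2-dominant, R2>1", "asymptotically stable",
          "Omega9", deg_R2)
    }
  } else {
    add("-", paste("regime", regime), "no row fires", "-",
        regime == "degenerate")
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(r, stringsAsFactors = FALSE)
  }))
  attr(out, "regime") <- regime
  out
}

# Regions whose stability claim confines the demand state to the stable
# manifold of the 2D saddle; there only the purchase block of the spectrum
# is decisive (the demand motion on the manifold converges to M).
separatrix_regions <- c("Omega12", "Omega13")

#' Cross-validate eigenvalue verdicts against the condition table
#'
#' Samples parameter sets from the requested regimes with
#' [sample_parameters()], classifies every fired condition-table row both
#' ways, and reports the agreement. For rows whose region is full-
#' dimensional the comparison is against the full-spectrum eigenvalue
#' verdict; for the separatrix-confined regions (Omega12/Omega13) it is
#' against the purchase-block verdict, since the full spectrum necessarily
#' contains the demand saddle's positive eigenvalue and the claim is
#' conditional on the demand state lying on the stable manifold.
#' Optionally each agreeing stable row is additionally checked by forward
#' simulation from seeded states inside the claimed region (see
#' [detect_convergence()]).
#'
#' @param regimes character vector of regime labels to sample from.
#' @param n_samples samples per regime.
#' @param seed integer seed for the sampler.
#' @param simulate integer: number of simulation spot-checks per regime
#'   (0 disables trajectory validation).
#' @param t_end horizon for the simulation spot-checks.
#' @return A list with `agreement` (fraction over non-degenerate rows),
#'   `n_rows`, `disagreements` (data frame, empty when all agree) and the
#'   per-row `details` data frame.
#' @export
cross_validate <- function(regimes = c("coexistence", "bistable",
                                       "channel1-dominant",
                                       "channel2-dominant"),
                           n_samples = 50, seed = 1,
                           simulate = 0, t_end = 2000) {
  details <- list()
  for (rg in regimes) {
    sets <- sample_parameters(rg, n_samples, seed = seed)
    for (k in seq_along(sets)) {
      p <- sets[[k]]
      tab <- classify_by_conditions(p)
      eq <- enumerate_equilibria_4d(p)
      for (i in seq_len(nrow(tab))) {
        row <- tab[i, ]
        if (row$point == "-" || row$degenerate) next
        pt <- eq[[row$point]]
        if (!isTRUE(pt$exists)) {
          details[[length(details) + 1L]] <- data.frame(
            regime = rg, sample = k, point = row$point, region = row$region,
            table_verdict = row$verdict, eigen_verdict = "point missing",
            agree = FALSE, stringsAsFactors = FALSE)
          next
        }
        rep <- classify_by_eigenvalues(pt, p)
        ev_verdict <- if (row$region %in% separatrix_regions) {
          rep$verdict_I
        } else {
          rep$verdict
        }
        details[[length(details) + 1L]] <- data.frame(
          regime = rg, sample = k, point = row$point, region = row$region,
          table_verdict = row$verdict, eigen_verdict = ev_verdict,
          agree = identical(row$verdict, ev_verdict) ||
            (row$verdict == "unstable" && ev_verdict %in%
               c("unstable", "saddle")),
          stringsAsFactors = FALSE)
      }
    }
    if (simulate > 0) {
      sim_sets <- sets[seq_len(min(simulate, length(sets)))]
      for (p in sim_sets) {
        chk <- check_convergence_rows(p, seed = seed, t_end = t_end)
        if (nrow(chk)) details[[length(details) + 1L]] <- chk
      }
    }
  }
  details <- do.call(rbind, details)
  rownames(details) <- NULL
  list(agreement = mean(details$agree), n_rows = nrow(details),
       disagreements = details[!details$agree, , drop = FALSE],
       details = details)
}

# Simulation leg of the cross-validation: for each stable condition-table
# row, integrate from states inside the claimed region and require
# convergence to the claimed point. Separatrix-confined rows are checked on
# the purchase subsystem with the demand state held at M (the limit of the
# motion on the stable manifold).
check_convergence_rows <- function(params, seed = 1, t_end = 2000,
                                   n_states = 3) {
  p <- validate_params(params)
  tab <- classify_by_conditions(p)
  eq <- enumerate_equilibria_4d(p)
  part <- NULL
  out <- list()
  set.seed(seed)
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    if (row$point == "-" || row$degenerate ||
        row$verdict != "asymptotically stable") next
    pt <- eq[[row$point]]
    if (!isTRUE(pt$exists)) next
    # horizon keyed to the target's slowest contraction rate; claims too
    # close to the stability boundary cannot be resolved by finite-time
    # simulation and are skipped as numerically degenerate
    rep <- classify_by_eigenvalues(pt, p)
    rate <- if (row$region %in% separatrix_regions) {
      min(abs(Re(rep$eigenvalues_I)))
    } else {
      min(abs(Re(rep$eigenvalues)))
    }
    if (rate < 3e-4) next
    t_use <- min(max(t_end, 30 / rate), 1e5)
    if (row$region %in% separatrix_regions) {
      ok <- converges_on_manifold(p, pt, t_use)
      out[[length(out) + 1L]] <- data.frame(
        regime = attr(tab, "regime"), sample = NA_integer_,
        point = row$point, region = paste0(row$region, " (simulated)"),
        table_verdict = row$verdict,
        eigen_verdict = if (ok) "converged" else "did not converge",
        agree = ok, stringsAsFactors = FALSE)
      next
    }
    if (row$region %in% c("Omega2", "Omega3", "Omega6", "Omega7") &&
        is.null(part)) {
      M <- demand_equilibria_2d(p)$M
      part <- try(separatrix_2d(p, M), silent = TRUE)
      if (inherits(part, "try-error")) part <- NULL
    }
    states <- sample_states_in_region(row$region, p, part, n_states)
    for (s in states) {
      traj <- simulate_sis(p, s, t_end = t_use, grid = 400)
      hit <- detect_convergence(traj, eq, tol = 1e-3)
      ok <- identical(hit, row$point)
      out[[length(out) + 1L]] <- data.frame(
        regime = attr(tab, "regime"), sample = NA_integer_,
        point = row$point, region = paste0(row$region, " (simulated)"),
        table_verdict = row$verdict,
        eigen_verdict = if (ok) "converged" else paste("converged to", hit),
        agree = ok, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(regime = character(), sample = integer(),
                      point = character(), region = character(),
                      table_verdict = character(),
                      eigen_verdict = character(), agree = logical()))
  }
  do.call(rbind, out)
}

# Purchase subsystem with demand pinned at M: the asymptotic dynamics on
# the separatrix (demand converges to M along the stable manifold).
converges_on_manifold <- function(p, pt, t_end) {
  N1E <- pt$coords[["N1"]]; N2E <- pt$coords[["N2"]]
  rhs <- function(t, y, parms) {
    dI1 <- (p$beta11 * y[1] + p$beta12 * y[2]) * (N1E - y[1]) -
      p$gamma1 * y[1]
    dI2 <- (p$beta21 * y[1] + p$beta22 * y[2]) * (N2E - y[2]) -
      p$gamma2 * y[2]
    list(c(dI1, dI2))
  }
  y0 <- c(I1 = 0.05 * N1E, I2 = 0.05 * N2E)
  sol <- deSolve::lsoda(y0, seq(0, t_end, length.out = 200), rhs, NULL,
                        rtol = 1e-9, atol = 1e-12, maxsteps = 100000)
  term <- sol[nrow(sol), c("I1", "I2")]
  target <- pt$coords[c("I1", "I2")]
  scale <- max(1, N1E, N2E)
  sqrt(sum((term - target)^2)) < 1e-3 * scale
}

# Draw interior states satisfying an Omega-region predicate; basin-confined
# regions use the basin partition.
sample_states_in_region <- function(region, p, part, n_states) {
  states <- list()
  tries <- 0L
  while (length(states) < n_states && tries < 400L) {
    tries <- tries + 1L
    N1 <- stats::runif(1, 0.02, 0.98) * p$K1
    N2 <- stats::runif(1, 0.02, 0.98) * p$K2
    I1 <- stats::runif(1, 0.01, 0.9) * N1
    I2 <- stats::runif(1, 0.01, 0.9) * N2
    st <- c(N1 = N1, I1 = I1, N2 = N2, I2 = I2)
    ok <- switch(region,
      Omega2 = , Omega3 = !is.null(part) &&
        basin_label(c(N1, N2), part) == "Y",
      Omega6 = , Omega7 = !is.null(part) &&
        basin_label(c(N1, N2), part) == "X",
      Omega4 = , Omega5 = , Omega8 = , Omega9 = ,
      Omega10 = , Omega11 = TRUE,
      FALSE)
    if (isTRUE(ok)) states[[length(states) + 1L]] <- st
  }
  states
}
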