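test_that("reproduction numbers follow beta*K/gamma", {
  expect_equal(unname(reproduction_numbers(params_s51())),
               c(0.5, 0.05 * 1000 / 0.01))
  expect_equal(reproduction_numbers(params_s51(beta11 = 0))[["R1"]], 0)
  expect_equal(reproduction_numbers(
    params_s51(beta22 = 3e-05))[["R2"]], 3)
})

test_that("interior demand equilibrium matches an independent nullcline solve", {
  p <- params_s51()
  eq <- demand_equilibria_2d(p)
  expect_equal(attr(eq, "regime"), "bistable")
  expect_true(eq$M$exists)
  # oracle: solve the linear per-capita nullcline system directly
  A <- rbind(c(-p$r1 / p$K1, p$m / p$K2), c(p$n / p$K1, -p$r2 / p$K2))
  oracle <- solve(A, c(-p$r1, -p$r2))
  expect_equal(unname(eq$M$coords), oracle, tolerance = 1e-12)
  expect_equal(unname(eq$M$coords), c(250, 625))
})

test_that("existence of M follows the competition regimes", {
  # no cross-influence: formula reduces to (K1, K2) but M needs competition
  eq0 <- demand_equilibria_2d(params_s51(m = 0, n = 0))
  expect_equal(unname(eq0$M$coords), c(1000, 1000))
  expect_false(eq0$M$exists)
  # online-dominant set: three equilibria only
  eq52 <- demand_equilibria_2d(params_s52())
  expect_equal(attr(eq52, "regime"), "channel2-dominant")
  expect_false(eq52$M$exists)
  n_exist <- sum(vapply(eq52, function(e) e$exists, logical(1)))
  expect_equal(n_exist, 3)
})

test_that("equilibrium counts per regime hold over seeded samples", {
  for (p in sample_parameters("coexistence", 30, seed = 101)) {
    eq <- demand_equilibria_2d(p)
    pts <- Filter(function(e) e$exists, eq)
    expect_equal(length(pts), 4)
    # pairwise distinct
    co <- do.call(rbind, lapply(pts, function(e) e$coords))
    dmin <- min(stats::dist(co))
    expect_gt(dmin, 1e-6 * max(p$K1, p$K2))
  }
  for (rg in c("channel1-dominant", "channel2-dominant")) {
    for (p in sample_parameters(rg, 15, seed = 102)) {
      n_exist <- sum(vapply(demand_equilibria_2d(p), function(e) e$exists,
                            logical(1)))
      expect_equal(n_exist, 3)
    }
  }
})

test_that("boundary purchase equilibria follow the reproduction thresholds", {
  # at threshold the endemic point collapses onto the purchase-free one
  p_thr <- params_s51(beta11 = 0.01 / 1000)
  b <- boundary_infected_equilibria(p_thr)
  expect_false(b$P2$exists)
  expect_equal(b$P2$coords[["I1"]], 0)
  # R1 = 3
  p3 <- params_s51(beta11 = 3e-05)
  expect_equal(boundary_infected_equilibria(p3)$P2$coords[["I1"]],
               1000 * (1 - 1 / 3))
  # published sub-threshold value
  expect_false(boundary_infected_equilibria(params_s51())$P2$exists)
  # the channel-2 endemic level scales with K2, not K1
  pk <- params_s51(K1 = 400, K2 = 1600, beta22 = 2e-05, gamma2 = 0.004)
  R2 <- 2e-05 * 1600 / 0.004
  expect_equal(boundary_infected_equilibria(pk)$P4$coords[["I2"]],
               1600 * (1 - 1 / R2))
})

test_that("endemic level is continuous and increasing in R1 and vanishes at threshold", {
  set.seed(33)
  K1 <- 1000; gamma1 <- 0.01
  R1s <- sort(stats::runif(50, 1.0001, 12))
  I1Es <- vapply(R1s, function(R1) {
    p <- params_s51(beta11 = R1 * gamma1 / K1)
    boundary_infected_equilibria(p)$P2$coords[["I1"]]
  }, numeric(1))
  expect_true(all(diff(I1Es) > 0))
  # each matches the nonzero root of beta11*I1*(K1 - I1) - gamma1*I1 = 0
  for (i in seq_along(R1s)) {
    beta11 <- R1s[i] * gamma1 / K1
    root <- stats::uniroot(function(I1) beta11 * I1 * (K1 - I1) - gamma1 * I1,
                           c(1e-6, K1 - 1e-9), tol = 1e-12)$root
    expect_equal(I1Es[i], root, tolerance = 1e-8)
  }
  # limit from above
  p_near <- params_s51(beta11 = (1 + 1e-9) * gamma1 / K1)
  expect_lt(boundary_infected_equilibria(p_near)$P2$coords[["I1"]], 1e-5 * K1)
})

test_that("invasion balance terms collapse to the recovery rates at M", {
  for (rg in c("coexistence", "bistable")) {
    for (p in sample_parameters(rg, 20, seed = 55)) {
      th <- interior_thresholds(p)
      expect_equal(th$A, p$gamma1, tolerance = 1e-9)
      expect_equal(th$B, p$gamma2, tolerance = 1e-9)
    }
  }
  # division guard
  th0 <- interior_thresholds(params_s53(beta12 = 0))
  expect_true("Pi1" %in% th0$undefined)
  expect_true(is.na(th0$Pi1))
})

test_that("published cross-channel set crosses the invasion threshold", {
  th <- interior_thresholds(params_s53(beta12 = 5e-05, beta21 = 5e-05))
  expect_true(th$A_cond && th$B_cond)
  expect_lt(th$Pi1, th$Pi2)
})

test_that("interior purchase equilibrium is found by bracketed solve and zeroes the RHS", {
  p <- params_s53(beta12 = 5e-05, beta21 = 5e-05)
  P6 <- interior_infected_equilibrium(p)
  expect_true(P6$exists)
  expect_lt(rhs_norm(rhs_4d(P6$coords, p)),
            1e-9 * max(1, rhs_norm(P6$coords)))
  # oracle: dense grid search for the joint sign structure
  N1E <- P6$coords[["N1"]]; N2E <- P6$coords[["N2"]]
  f1 <- function(I1, I2) (p$beta11 * I1 + p$beta12 * I2) * (N1E - I1) -
    p$gamma1 * I1
  f2 <- function(I1, I2) (p$beta21 * I1 + p$beta22 * I2) * (N2E - I2) -
    p$gamma2 * I2
  g1 <- seq(1e-3, N1E - 1e-3, length.out = 400)
  g2 <- seq(1e-3, N2E - 1e-3, length.out = 400)
  res <- outer(g1, g2, function(a, b) abs(f1(a, b)) + abs(f2(a, b)))
  idx <- which(res == min(res), arr.ind = TRUE)
  expect_equal(unname(P6$coords[["I1"]]), g1[idx[1]],
               tolerance = 2 * diff(g1[1:2]) / g1[idx[1]])
  expect_equal(unname(P6$coords[["I2"]]), g2[idx[2]],
               tolerance = 2 * diff(g2[1:2]) / g2[idx[2]])
})

test_that("interior purchase equilibrium respects decoupling and the Pi threshold", {
  # sub-threshold: the base published cross-channel set has Pi1 > Pi2
  base <- params_s53()
  th <- interior_thresholds(base)
  expect_gt(th$Pi1, th$Pi2)
  expect_false(interior_infected_equilibrium(base)$exists)
  # decoupled channels: closed forms
  p <- params_s53(beta11 = 5e-05, beta22 = 3e-05, beta12 = 0, beta21 = 0)
  M <- demand_equilibria_2d(p)$M
  N1E <- M$coords[["N1"]]; N2E <- M$coords[["N2"]]
  P6 <- interior_infected_equilibrium(p)
  expect_true(P6$exists)
  expect_equal(P6$coords[["I1"]], N1E * (1 - p$gamma1 / (p$beta11 * N1E)),
               tolerance = 1e-9)
  expect_equal(P6$coords[["I2"]], N2E * (1 - p$gamma2 / (p$beta22 * N2E)),
               tolerance = 1e-9)
})

test_that("the seven-point enumeration carries correct existence verdicts", {
  eq51 <- enumerate_equilibria_4d(params_s51())
  for (lab in c("P0", "P1", "P3", "P5")) expect_true(eq51[[lab]]$exists)
  expect_false(eq51$P2$exists)
  expect_match(eq51$P2$violated, "R1")
  # no transmission at all: only the purchase-free points remain
  p0 <- params_s51(beta11 = 0, beta12 = 0, beta21 = 0, beta22 = 0)
  eq0 <- enumerate_equilibria_4d(p0)
  expect_equal(vapply(eq0, function(e) e$exists, logical(1)),
               c(P0 = TRUE, P1 = TRUE, P2 = FALSE, P3 = TRUE, P4 = FALSE,
                 P5 = TRUE, P6 = FALSE))
  # strong cross-channel set: all seven
  eq53 <- enumerate_equilibria_4d(params_s53(beta11 = 3e-05, beta22 = 3e-05,
                                             beta12 = 5e-05, beta21 = 5e-05))
  expect_true(all(vapply(eq53, function(e) e$exists, logical(1))))
})

test_that("every existing equilibrium zeroes the RHS and lies in its region", {
  regimes <- c("coexistence", "bistable", "channel1-dominant",
               "channel2-dominant")
  for (rg in regimes) {
    for (p in sample_parameters(rg, 25, seed = 77)) {
      eq <- enumerate_equilibria_4d(p)
      for (e in eq) {
        if (!e$exists) next
        expect_lt(rhs_norm(rhs_4d(e$coords, p)),
                  1e-9 * max(1, rhs_norm(e$coords)))
        expect_true(in_region(e$coords, p, tol = 1e-9))
      }
    }
  }
})

test_that("Pi ordering is equivalent to the next-generation spectral radius", {
  n_checked <- 0
  for (p in sample_parameters("coexistence", 150, seed = 88)) {
    th <- interior_thresholds(p)
    if (!th$A_cond || !th$B_cond || length(th$undefined)) next
    M <- demand_equilibria_2d(p)$M
    N1E <- M$coords[["N1"]]; N2E <- M$coords[["N2"]]
    NG <- rbind(c(p$beta11 * N1E / p$gamma1, p$beta12 * N1E / p$gamma1),
                c(p$beta21 * N2E / p$gamma2, p$beta22 * N2E / p$gamma2))
    rho <- max(abs(eigen(NG, only.values = TRUE)$values))
    expect_equal(th$Pi1 < th$Pi2, rho > 1)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 15)
})
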