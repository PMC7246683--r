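test_that("an equilibrium initial condition yields a constant trajectory", {
  p <- params_s51(beta11 = 3e-05)
  eq <- enumerate_equilibria_4d(p)
  traj <- simulate_sis(p, eq$P2$coords, t_end = 100, grid = 50)
  for (v in c("N1", "I1", "N2", "I2")) {
    expect_equal(traj[[v]], rep(eq$P2$coords[[v]], nrow(traj)),
                 tolerance = 1e-7)
  }
})

test_that("single-channel reduction conserves S + I and follows the logistic solution", {
  # channel 2 empty and no cross-transmission: channel 1 is a classical SIS
  # system on a fixed population K1
  p <- params_s51(beta11 = 3e-05, beta12 = 0, beta21 = 0, beta22 = 0)
  I0 <- 5
  traj <- simulate_sis(p, c(N1 = p$K1, I1 = I0, N2 = 0, I2 = 0),
                       t_end = 400, grid = 400)
  expect_equal(traj$N1, rep(p$K1, nrow(traj)), tolerance = 1e-6)
  S_plus_I <- (traj$N1 - traj$I1) + traj$I1
  expect_lt(max(abs(S_plus_I - p$K1)), 1e-6 * p$K1)
  # closed-form SIS solution: dI = (rho - beta*I) I with rho = beta*K - gamma
  rho <- p$beta11 * p$K1 - p$gamma1
  I_exact <- rho * I0 * exp(rho * traj$time) /
    (rho + p$beta11 * I0 * (exp(rho * traj$time) - 1))
  expect_equal(traj$I1, I_exact, tolerance = 1e-6)
})

test_that("direct integration of the single-channel model conserves the population", {
  p <- single_channel_params(beta = 3e-05, gamma = 0.01, N = 1000)
  rhs <- function(t, y, parms) list(unname(sis_rhs_single(y, p)))
  sol <- deSolve::lsoda(c(S = 995, I = 5), seq(0, 1000, length.out = 200),
                        rhs, NULL, rtol = 1e-9, atol = 1e-12)
  expect_lt(max(abs(sol[, "S"] + sol[, "I"] - 1000)), 1e-6 * 1000)
})

test_that("total sales series sums the purchase counts", {
  p <- params_s53(beta12 = 5e-05, beta21 = 5e-05)
  # purchase-free start stays purchase-free
  tr0 <- simulate_sis(p, c(N1 = 100, I1 = 0, N2 = 100, I2 = 0),
                      t_end = 20, grid = 50)
  expect_equal(total_sales_series(tr0)$total_sales, rep(0, 50))
  # started at the interior purchase equilibrium the series is constant
  P6 <- interior_infected_equilibrium(p)
  tr6 <- simulate_sis(p, P6$coords, t_end = 50, grid = 50)
  expect_equal(total_sales_series(tr6)$total_sales,
               rep(P6$coords[["I1"]] + P6$coords[["I2"]], 50),
               tolerance = 1e-6)
  expect_true(all(total_sales_series(tr6)$total_sales >= 0))
})

test_that("convergence detection matches trajectories to their attractor", {
  # sub-threshold offline scenario settles at the purchase-free point
  p <- params_s51()
  eq <- enumerate_equilibria_4d(p)
  traj <- simulate_sis(p, c(N1 = 100, I1 = 1, N2 = 100, I2 = 1),
                       t_end = 4000, grid = 400)
  expect_equal(detect_convergence(traj, eq), "P1")
  # too short a horizon gives no match
  short <- simulate_sis(p, c(N1 = 100, I1 = 1, N2 = 100, I2 = 1),
                        t_end = 5, grid = 50)
  expect_equal(detect_convergence(short, eq), "none")
  # bistable with R2 > 1, started in the online basin, settles at P4
  p2 <- params_s51(beta22 = 3e-05)
  eq2 <- enumerate_equilibria_4d(p2)
  traj2 <- simulate_sis(p2, c(N1 = 50, I1 = 1, N2 = 800, I2 = 1),
                        t_end = 4000, grid = 400)
  expect_equal(detect_convergence(traj2, eq2), "P4")
})

test_that("nullclines are the published straight lines and meet at M", {
  # without cross-influence the interior demand nullcline is the vertical
  # line at carrying capacity
  nc0 <- nullclines_2d(params_s51(m = 0), grid = 11)
  int0 <- subset(nc0$N1_null, branch == "interior")
  expect_true(all(int0$N1 == 1000))
  # published bistable set: intersection at M
  nc <- nullclines_2d(params_s51(), grid = 31)
  expect_equal(unname(nc$intersection), c(250, 625))
  # interior points satisfy the line equations
  p <- params_s51()
  int1 <- subset(nc$N1_null, branch == "interior")
  expect_true(all(abs(p$r1 * (1 - int1$N1 / p$K1) +
                        p$m * int1$N2 / p$K2) < 1e-12))
  # channel-dominant set: intersection outside G, M nonexistent
  p52 <- params_s52()
  nc52 <- nullclines_2d(p52)
  inter <- nc52$intersection
  expect_false(inter[["N1"]] >= 0 && inter[["N1"]] <= p52$K1 &&
                 inter[["N2"]] >= 0 && inter[["N2"]] <= p52$K2)
  expect_false(demand_equilibria_2d(p52)$M$exists)
})

test_that("separatrix assigns basins consistently with forward simulation", {
  p <- params_s51()
  part <- separatrix_2d(p)
  expect_equal(basin_label(part$M, part), "separatrix")
  # both branches terminate at M (curve midpoint)
  for (b in part$branches) {
    expect_lt(sqrt(sum((as.numeric(b[nrow(b), ]) - part$M)^2)),
              1e-3 * max(p$K1, p$K2))
  }
  set.seed(41)
  n_checked <- 0
  for (i in 1:12) {
    st <- c(stats::runif(1, 0.02, 0.98) * p$K1,
            stats::runif(1, 0.02, 0.98) * p$K2)
    lab <- basin_label(st, part)
    if (lab == "separatrix") next
    term <- terminal_2d(st, p)
    attractor <- if (term[1] > term[2]) "Y" else "X"
    expect_identical(lab, attractor)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 8)
  # near-corner starts converge to the offline attractor P
  expect_identical(basin_label(c(0.99 * p$K1, 1), part), "Y")
})

test_that("separatrix of a symmetric system is symmetric under channel swap", {
  p <- model_params(1, 1, 1000, 1000, -1.5, -1.5, 1e-05, 1e-05, 1e-05,
                    1e-05, 0.01, 0.01)
  part <- separatrix_2d(p)
  expect_equal(unname(part$M), c(400, 400))
  # the mirrored curve lies on the curve itself
  idx <- seq(1, nrow(part$curve), length.out = 40)
  for (i in idx) {
    pt <- as.numeric(part$curve[i, ])
    expect_lt(point_dist_to_curve(rev(pt), part$curve),
              1e-3 * max(p$K1, p$K2))
  }
})

test_that("Omega-region membership follows the printed predicates", {
  p <- params_s51()
  part <- separatrix_2d(p)
  interior <- c(N1 = 400, I1 = 100, N2 = 300, I2 = 50)
  labs <- omega_region_membership(interior, p, part)
  expect_true(all(c("Omega1", "Omega4", "Omega5", "Omega8", "Omega9",
                    "Omega10", "Omega11") %in% labs))
  # a purchase-free channel drops the I-dependent regions
  labs0 <- omega_region_membership(c(400, 0, 300, 50), p, part)
  expect_false(any(c("Omega5", "Omega11", "Omega13") %in% labs0))
  # a state over the separatrix carries the manifold labels
  on_curve <- part$curve[nrow(part$curve) %/% 2, ]
  labs_sep <- omega_region_membership(
    c(on_curve$N1, 10, on_curve$N2, 10), p, part)
  expect_true(all(c("Omega12", "Omega13") %in% labs_sep))
  # basin labels need a partition when explicitly requested
  expect_error(omega_region_membership(interior, p, labels = "Omega2"),
               "partition")
  expect_setequal(omega_region_membership(interior, p, labels = "Omega4"),
                  "Omega4")
})

test_that("terminal states are robust to halving the solver tolerances", {
  cfg <- scenario_config("s51")
  for (b11 in c(5e-06, 9e-05)) {
    p <- params_s51(beta11 = b11)
    t1 <- simulate_sis(p, cfg$state0, cfg$t_end, grid = 200)
    t2 <- simulate_sis(p, cfg$state0, cfg$t_end, grid = 200,
                       rtol = 5e-10, atol = 5e-13)
    s1 <- as.numeric(t1[nrow(t1), c("N1", "I1", "N2", "I2")])
    s2 <- as.numeric(t2[nrow(t2), c("N1", "I1", "N2", "I2")])
    expect_lt(max(abs(s1 - s2)) / max(abs(s1), 1), 1e-5)
  }
})

test_that("trajectory export writes the CSV columns and JSON metadata", {
  p <- params_s51()
  traj <- simulate_sis(p, c(N1 = 100, I1 = 1, N2 = 100, I2 = 1),
                       t_end = 10, grid = 20)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "traj.csv")
  write_trajectory(traj, path)
  out <- utils::read.csv(path)
  expect_named(out, c("t", "N1", "I1", "N2", "I2", "total_sales"))
  expect_equal(out$total_sales, out$I1 + out$I2)
  meta <- jsonlite::fromJSON(file.path(dir, "traj.json"))
  expect_equal(meta$params$m, -1.2)
})
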