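test_that("the wall law round-trips and hits its reference points", {
  K <- 8e5
  A0 <- pi * 0.9^2
  expect_equal(wall_pressure(A0, K, A0), 0)
  expect_equal(wall_pressure(4 * A0, K, A0), (4 / 3) * K)
  p <- seq(-0.9 * K, 2.9 * K, length.out = 101)
  expect_equal(wall_pressure(wall_area(p, K, A0), K, A0), p, tolerance = 1e-12)
  expect_error(wall_area(-(4 / 3) * K, K, A0), "collapse")
})

test_that("a uniform rest state is preserved exactly", {
  Tp <- 0.3
  q0 <- rep(0, 64)
  sol <- simulate_single_vessel(5, 0.5, 8e5, q0, Tp, outlet = "nonreflecting",
                                numerics = solver_numerics(n_time = 64,
                                                           max_cycles = 3,
                                                           tol_periodic = 1e-12))
  expect_equal(max(abs(sol$fields$V1$q)), 0)
  expect_equal(max(abs(sol$fields$V1$A - sol$disc$A0)), 0)
})

test_that("small pulses propagate at the linearized wave speed", {
  K <- 8e5
  rho <- blood_properties()$rho
  c0 <- sqrt(2 * K / (3 * rho))
  Tp <- 0.2
  n <- 2048
  t <- (0:(n - 1)) * Tp / n
  q <- 2 * exp(-((t - 0.02) / 0.004)^2)
  sol <- simulate_single_vessel(20, 0.5, K, q, Tp, outlet = "nonreflecting",
                                numerics = solver_numerics(n_time = 2048,
                                                           dx_max = 0.1,
                                                           max_cycles = 2,
                                                           tol_periodic = 1e9))
  fl <- sol$fields$V1
  dx <- sol$disc$dx
  j1 <- round(5 / dx) + 1
  j2 <- round(15 / dx) + 1
  t1 <- t[which.max(fl$p[j1, ])]
  t2 <- t[which.max(fl$p[j2, ])]
  expect_equal(10 / (t2 - t1), c0, tolerance = 0.01)
})

test_that("the scheme converges at second order on a smooth pulse", {
  K <- 8e5
  Tp <- 0.4
  n <- 1024
  t <- (0:(n - 1)) * Tp / n
  q <- 5 * exp(-((t - 0.08) / 0.02)^2)
  run <- function(div) {
    simulate_single_vessel(10, 0.5, K, q, Tp, outlet = "nonreflecting",
                           numerics = solver_numerics(n_time = 512,
                                                      dx_max = 10 / div,
                                                      min_divisions = div,
                                                      cfl = 0.4, max_cycles = 2,
                                                      tol_periodic = 1e9))
  }
  p1 <- run(16)$fields$V1$p[9, ]
  p2 <- run(32)$fields$V1$p[17, ]
  p3 <- run(64)$fields$V1$p[33, ]
  order <- log2(sqrt(mean((p1 - p2)^2)) / sqrt(mean((p2 - p3)^2)))
  expect_gte(order, 1.8)
})

test_that("a symmetric bifurcation splits flow exactly in half", {
  net <- make_toy_network(2)
  num <- coarse_numerics()
  sol <- simulate_network(net, default_theta(), default_waveforms(), num)
  q2 <- vessel_trace(sol, "A2")$q
  q3 <- vessel_trace(sol, "A3")$q
  qp <- vessel_trace(sol, "A1", "outlet")$q
  expect_equal(q2, q3, tolerance = 1e-10)
  q2in <- vessel_trace(sol, "A2", "inlet")$q
  q3in <- vessel_trace(sol, "A3", "inlet")$q
  expect_equal(qp, q2in + q3in, tolerance = 1e-8)
  # pressure continuity at the junction
  pp <- vessel_trace(sol, "A1", "outlet")$p
  p2 <- vessel_trace(sol, "A2", "inlet")$p
  expect_equal(pp, p2, tolerance = 1e-8)
})

test_that("the toy network conserves mass and reaches a periodic state", {
  net <- make_toy_network(1)
  sol <- simulate_network(net, default_theta(), default_waveforms(),
                          coarse_numerics())
  expect_true(sol$converged)
  expect_lt(flow_balance(sol)$rel_error, 0.01)
  # pressure and area consistent with the wall law at every stored node
  fl <- sol$fields$A1
  K <- sol$K[["A1"]]
  expect_equal(fl$p, wall_pressure(fl$A, K, sol$disc$A0[1]), tolerance = 1e-12)
})

test_that("vein roots hold the prescribed left-atrial pressure", {
  sol <- coarse_solution()
  pla <- sol$waveforms$p_la
  for (nm in sol$network$vein_roots) {
    pv <- vessel_trace(sol, nm, "outlet")$p
    expect_equal(pv, pla, tolerance = 1e-9)
  }
  # prescribed inlet flow is honoured
  qin <- vessel_trace(sol, "MPA", "inlet")$q
  expect_equal(qin, sol$waveforms$q_inlet, tolerance = 1e-9)
  expect_equal(mean(qin), mean(sol$waveforms$q_inlet), tolerance = 5e-3)
})

test_that("cycle-averaged pressure falls from the root to every terminal artery", {
  sol <- coarse_solution()
  p_mpa <- mean(vessel_trace(sol, "MPA", "inlet")$p)
  for (b in sol$network$beds$artery) {
    expect_lt(mean(vessel_trace(sol, b, "outlet")$p), p_mpa)
  }
})

test_that("theta vectors outside the prior bounds are rejected", {
  th <- default_theta()
  th[["alpha"]] <- 0.99
  expect_error(simulate_network(full_network(), th), "bounds")
  th <- default_theta()
  th[["beta"]] <- th[["alpha"]]
  th[["alpha"]] <- 0.81
  expect_error(pulmtree:::validate_theta(th), "bounds|beta")
})
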