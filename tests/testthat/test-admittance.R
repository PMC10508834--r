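test_that("the Womersley factor matches a high-precision series oracle", {
  blood <- blood_properties()
  for (om in c(1, 10, 50, 200)) {
    for (r in c(0.005, 0.02, 0.05)) {
      mu <- viscosity_law(r, blood)
      expect_lt(Mod(womersley_factor(om, r, blood, mu) -
                      womersley_series(om, r, blood$rho, mu)), 1e-12)
    }
  }
})

test_that("the Womersley factor has the correct limits", {
  blood <- blood_properties()
  # flat-profile limit
  expect_lt(Mod(womersley_factor(1e7, 1, blood) - 1), 1e-2)
  # low-frequency limit F -> -w0^2/8 makes the admittance Poiseuille
  r <- 0.01
  mu <- blood$mu
  Fs <- womersley_factor(1e-8, r, blood, mu)
  w0sq <- complex(imaginary = -1) * r^2 * 1e-8 * blood$rho / mu
  expect_equal(Fs, -w0sq / 8, tolerance = 1e-6)
})

test_that("the viscosity law is positive, continuous, and has the bulk limit", {
  blood <- blood_properties()
  expect_equal(viscosity_law(0.3, blood, "constant"), blood$mu)
  expect_equal(blood$mu, 1.055 * 3.03e-2)
  expect_equal(blood$mu, 0.031967, tolerance = 2e-5)
  r <- exp(seq(log(1e-3), log(1), length.out = 200))
  mu <- viscosity_law(r, blood, "radius")
  expect_true(all(mu > 0))
  expect_lt(max(abs(diff(mu)) / mu[-1]), 0.2)  # no jumps on a log grid
  expect_lt(abs(viscosity_law(1, blood, "radius") - blood$mu) / blood$mu, 0.15)
  expect_error(viscosity_law(-0.1, blood), "positive")
})

test_that("single-vessel admittance is symmetric with the Poiseuille zero mode", {
  grid <- frequency_grid(0.85, 64)
  blood <- blood_properties()
  Y <- vessel_admittance(0.01, 0.2, 2.5e5, grid, blood, "constant")
  G0 <- pi * 0.01^4 / (8 * blood$mu * 0.2)
  expect_equal(Re(Y$y11[1]), G0, tolerance = 1e-12)
  expect_equal(Y$y12[1], complex(real = -G0))
  expect_equal(Y$y12, Y$y21)
  # no flow under uniform pressure at omega = 0
  expect_equal(Mod(Y$y11[1] + Y$y12[1]), 0)
  expect_true(all(is.finite(Mod(Y$y11))), all(is.finite(Mod(Y$y12))))
})

test_that("the oscillatory admittance tends to the Poiseuille matrix as omega -> 0", {
  grid_lo <- frequency_grid(1e6, 8)  # omega_1 = 2 pi / T ~ 6e-6 rad/s
  Y <- vessel_admittance(0.01, 0.2, 2.5e5, grid_lo, viscosity_mode = "constant")
  expect_equal(Y$y11[2], Y$y11[1], tolerance = 1e-6)
  expect_equal(Y$y12[2], Y$y12[1], tolerance = 1e-6)
})

test_that("grand admittance equals the directly assembled network solution", {
  grid <- frequency_grid(0.85, 64)
  bed <- small_bed()
  for (mode in c("constant", "radius")) {
    Y <- grand_admittance(bed$at, bed$vt, 2.5e5, grid, viscosity_mode = mode)
    O <- direct_grand_oracle(bed$at, bed$vt, 2.5e5, grid, mode)
    rel <- Mod(grand_as_matrix(Y) - O) / pmax(Mod(O), .Machine$double.xmin)
    expect_lt(max(rel), 1e-10)
  }
})

test_that("a depth-0 bed reduces to the series Poiseuille conductance", {
  grid <- frequency_grid(0.85, 16)
  blood <- blood_properties()
  at <- generate_tree(0.05, 0.85, 0.68, 20, r_min = 0.045)
  vt <- mirror_tree(at, 0.04, 25)
  expect_equal(nrow(at$nodes), 1)
  Y <- grand_admittance(at, vt, 2.5e5, grid, viscosity_mode = "constant")
  Ra <- 8 * blood$mu * at$nodes$length_cm / (pi * 0.05^4)
  Rv <- 8 * blood$mu * vt$nodes$length_cm / (pi * 0.04^4)
  G <- 1 / (Ra + Rv)
  expect_equal(Re(Y$y11[1]), G, tolerance = 1e-12)
  expect_equal(Re(Y$y12[1]), -G, tolerance = 1e-12)
  # uniform pressure at both ports drives no flow
  expect_equal(Mod(Y$y11[1] + Y$y12[1]), 0, tolerance = 1e-25)
})

test_that("the bed is passive and its conductance is monotone in the geometry", {
  grid <- frequency_grid(0.85, 8)
  g0 <- function(alpha, beta, rmin) {
    at <- generate_tree(0.2, alpha, beta, 25, rmin)
    vt <- mirror_tree(at, 0.18, 25)
    Y <- grand_admittance(at, vt, 2.5e5, grid)
    M <- matrix(c(Y$y11[1], Y$y21[1], Y$y12[1], Y$y22[1]), 2, 2)
    ev <- eigen(Re(M), symmetric = TRUE)$values
    expect_gte(min(ev), -1e-12 * max(abs(ev)))
    Re(Y$y11[1])
  }
  expect_gt(g0(0.90, 0.65, 3e-3), g0(0.82, 0.65, 3e-3))
  expect_gt(g0(0.86, 0.70, 3e-3), g0(0.86, 0.60, 3e-3))
  # pruning the smallest generations removes series resistance on both sides
  # of the bed, so the zero-frequency conductance grows with the cutoff
  expect_gt(g0(0.86, 0.65, 8e-3), g0(0.86, 0.65, 1e-3))
  expect_gt(g0(0.92, 0.70, 8e-3), g0(0.92, 0.70, 1e-3))
})

test_that("batched tree segment admittances equal per-vessel evaluation", {
  grid <- frequency_grid(0.85, 32)
  blood <- blood_properties()
  at <- small_bed()$at
  seg <- pulmtree:::tree_segment_admittances(at, 2.5e5, grid, blood, "radius")
  for (b in c(1, 5, nrow(at$nodes))) {
    Y <- vessel_admittance(at$nodes$radius_cm[b], at$nodes$length_cm[b], 2.5e5,
                           grid, blood, "radius")
    expect_equal(seg$y11[, b], Y$y11, tolerance = 1e-13)
    expect_equal(seg$y12[, b], Y$y12, tolerance = 1e-13)
  }
})

test_that("time-domain kernels are real and reproduce harmonic responses", {
  grid <- frequency_grid(0.85, 128)
  bed <- small_bed()
  Y <- grand_admittance(bed$at, bed$vt, 2.5e5, grid)
  k <- admittance_to_time_domain(Y)
  expect_true(is.numeric(k$y11) && is.numeric(k$y22))
  n <- grid$n
  t <- (0:(n - 1)) * grid$dt
  # circular convolution of a pure harmonic maps through Y(omega_1)
  p1 <- cos(grid$omega[2] * t)
  conv <- function(kern, x) {
    idx <- outer(0:(n - 1), 0:(n - 1), function(a, b) (a - b) %% n + 1)
    as.vector(matrix(kern[idx], n, n) %*% x)
  }
  q <- conv(k$y11, p1)
  # expected: Re(Y11(w1) e^{i w1 t})
  expected <- Re(Y$y11[2] * exp(1i * grid$omega[2] * t))
  expect_equal(q, expected, tolerance = 1e-10)

  # frequency-flat (purely resistive) spectrum gives a lag-0 kernel
  Yr <- Y
  Yr$y11 <- rep(complex(real = 2.5), length(grid$omega))
  kr <- admittance_to_time_domain(Yr)
  expect_equal(kr$y11[1], 2.5, tolerance = 1e-12)
  expect_lt(max(abs(kr$y11[-1])), 1e-12)
})
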