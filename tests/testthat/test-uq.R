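test_that("prior samples honour the bounds and are reproducible", {
  s1 <- sample_prior(500, seed = 7)
  s2 <- sample_prior(500, seed = 7)
  expect_identical(s1, s2)
  b <- theta_bounds()
  for (p in b$parameter) {
    lo <- b$lower[b$parameter == p]
    up <- b$upper[b$parameter == p]
    expect_true(all(s1[[p]] >= lo & s1[[p]] <= up))
    expect_equal(mean(s1[[p]]), (lo + up) / 2,
                 tolerance = 0.02 * (up - lo) / ((lo + up) / 2) + 0.02)
  }
  expect_true(all(s1$alpha >= 0.80 & s1$alpha <= 0.92))
  expect_true(all(s1$rmin >= 1e-3 & s1$rmin <= 1e-2))
  bad <- b
  bad$lower[1] <- bad$upper[1]
  expect_error(sample_prior(10, bad), "bounds")
})

test_that("the basis has the right cardinality and empirical orthonormality", {
  expect_equal(nrow(build_basis(8, 4)$indices), 495)
  expect_equal(nrow(build_basis(8, 2)$indices), 45)
  expect_equal(nrow(build_basis(8, 3)$indices), choose(11, 3))
  b <- build_basis(3, 3, tibble::tibble(parameter = c("a", "b", "c"),
                                        lower = c(0, -2, 1), upper = c(1, 2, 4)))
  th <- withr::with_seed(99, cbind(runif(1e5), runif(1e5, -2, 2),
                                   runif(1e5, 1, 4)))
  Psi <- b$evaluate(th)
  Psi_n <- sweep(Psi, 2, sqrt(b$gamma), `/`)
  G <- crossprod(Psi_n) / nrow(Psi_n)
  expect_lt(max(abs(G - diag(ncol(G)))), 0.02)
})

test_that("polynomial targets are recovered exactly", {
  th <- sample_prior(600, seed = 5)
  y <- 3 + 2 * th$alpha + th$beta^2 * th$rmin + 0.5 * th$K_A / 1e6
  fit <- fit_pce_ols(th, y, build_basis(8, 3))
  expect_lt(max(abs(predict(fit, th) - y)) / diff(range(y)), 1e-8)
  # constant target: c0 carries it all, zero variance flagged downstream
  fitc <- fit_pce_ols(th, rep(4.2, nrow(th)), build_basis(8, 2))
  expect_equal(unname(fitc$coefficients[1, 1]), 4.2, tolerance = 1e-10)
  expect_lt(max(abs(fitc$coefficients[-1, 1])), 1e-10)
  m <- surrogate_moments(fitc)
  expect_equal(m$variance, 0, tolerance = 1e-18)
  expect_warning(sobol_from_pce(fitc), "zero-variance")
})

test_that("training-size and rank preconditions are enforced", {
  th <- sample_prior(50, seed = 3)
  expect_error(fit_pce_ols(th, th$alpha, build_basis(8, 3)), "training samples")
  expect_warning(fit_pce_ols(th, th$alpha, build_basis(8, 2)), "below 2J")
  thr <- th[rep(1, 50), ]  # degenerate design
  expect_error(suppressWarnings(fit_pce_ols(thr, thr$alpha, build_basis(8, 2))),
               "rank")
})

test_that("surrogate moments match closed forms and Monte Carlo", {
  th <- sample_prior(800, seed = 21)
  fit <- fit_pce_ols(th, th$K_A, build_basis(8, 2))
  m <- surrogate_moments(fit)
  b <- theta_bounds()
  expect_equal(m$mean, (5.6e5 + 1.04e6) / 2, tolerance = 1e-6)
  expect_equal(m$variance, (1.04e6 - 5.6e5)^2 / 12, tolerance = 1e-8)
  # MC check of the variance identity on a nonlinear surrogate
  y <- sin(4 * th$alpha) + th$rmin * 100
  fit2 <- suppressWarnings(fit_pce_ols(th, y, build_basis(8, 4)))
  big <- sample_prior(1e5, seed = 77)
  expect_equal(surrogate_moments(fit2)$variance, var(predict(fit2, big)),
               tolerance = 0.02)
})

test_that("Sobol' indices match analytic additive and Ishigami values", {
  b2 <- build_basis(2, 2, tibble::tibble(parameter = c("x1", "x2"),
                                         lower = c(0, 0), upper = c(1, 1)))
  X <- withr::with_seed(2, matrix(runif(400), 200, 2))
  z <- X[, 1] + 2 * X[, 2]
  s <- sobol_from_pce(fit_pce_ols(X, z, b2))
  expect_equal(unname(s$S[, 1]), c(0.2, 0.8), tolerance = 1e-10)
  expect_equal(unname(s$ST[, 1]), c(0.2, 0.8), tolerance = 1e-10)

  bI <- build_basis(3, 9, tibble::tibble(parameter = c("x1", "x2", "x3"),
                                         lower = rep(-pi, 3), upper = rep(pi, 3)))
  XI <- withr::with_seed(3, matrix(runif(12000, -pi, pi), ncol = 3))
  a <- 7; bb <- 0.1
  zI <- sin(XI[, 1]) + a * sin(XI[, 2])^2 + bb * XI[, 3]^4 * sin(XI[, 1])
  sI <- sobol_from_pce(fit_pce_ols(XI, zI, bI))
  V <- a^2 / 8 + bb * pi^4 / 5 + bb^2 * pi^8 / 18 + 0.5
  S_true <- c(0.5 * (1 + bb * pi^4 / 5)^2 / V, (a^2 / 8) / V, 0)
  ST_true <- c(S_true[1] + (8 * bb^2 * pi^8 / 225) / V, S_true[2],
               (8 * bb^2 * pi^8 / 225) / V)
  expect_equal(unname(sI$S[, 1]), S_true, tolerance = 0.02)
  expect_equal(unname(sI$ST[, 1]), ST_true, tolerance = 0.02)
})

test_that("PCE Sobol' indices agree with pick-freeze Monte Carlo on the surrogate", {
  b3 <- build_basis(3, 4, tibble::tibble(parameter = c("x1", "x2", "x3"),
                                         lower = rep(0, 3), upper = rep(1, 3)))
  X <- withr::with_seed(8, matrix(runif(1500), 500, 3))
  z <- exp(X[, 1]) + 3 * X[, 2] * X[, 1] + 0.5 * X[, 3]
  fit <- fit_pce_ols(X, z, b3)
  s <- sobol_from_pce(fit)
  pf <- pick_freeze_sobol(function(m) predict(fit, m), rep(0, 3), rep(1, 3),
                          n = 2e5, seed = 123)
  expect_equal(unname(s$S[, 1]), pf$S, tolerance = 0.02)
  expect_equal(unname(s$ST[, 1]), pf$ST, tolerance = 0.02)
})

test_that("index invariants hold for arbitrary fitted outputs", {
  th <- sample_prior(400, seed = 31)
  Y <- cbind(th$alpha^2 * th$K_A / 1e6, sin(th$beta * 5) + th$lrrA / 50,
             th$rmin * th$lrrV)
  s <- sobol_from_pce(fit_pce_ols(th, Y, build_basis(8, 3)))
  for (jcol in 1:3) {
    expect_true(all(s$S[, jcol] >= -1e-12))
    expect_true(all(s$S[, jcol] <= s$ST[, jcol] + 1e-6))
    expect_true(all(s$ST[, jcol] <= 1 + 1e-6))
    expect_lte(sum(s$S[, jcol]), 1 + 1e-6)
  }
})

test_that("generalized indices are variance-weighted averages of pointwise ones", {
  b2 <- build_basis(2, 2, tibble::tibble(parameter = c("x1", "x2"),
                                         lower = c(0, 0), upper = c(1, 1)))
  X <- withr::with_seed(4, matrix(runif(600), 300, 2))
  z <- X[, 1] + 2 * X[, 2]
  # time-constant indices: GS equals the pointwise value at every time
  fitc <- fit_pce_ols(X, cbind(z, 2 * z, 3 * z), b2)
  g <- generalized_sobol(fitc, times = c(0, 0.4, 1))
  expect_equal(unname(g$final$GS), c(0.2, 0.8), tolerance = 1e-10)
  expect_equal(unname(g$GS[, 2]), c(0.2, 0.8), tolerance = 1e-10)
  # two-segment construction: variance concentrated late pulls GS to the
  # late-segment indices (here segment 2 is x2-dominated and 100x stronger)
  z1 <- X[, 1]
  z2 <- 10 * X[, 2]
  fit2 <- fit_pce_ols(X, cbind(z1, z1, z2, z2), b2)
  g2 <- generalized_sobol(fit2, times = c(0, 0.01, 0.02, 1))
  v1 <- 1 / 12; v2 <- 100 / 12
  num1 <- v1 * 0.01 + v1 * 0.005          # trapezoids: x1 variance early
  num2 <- v2 * 0.005 + v2 * 0.98          # x2 variance late (dominant)
  den <- v1 * 0.015 + v2 * 0.985
  expect_equal(unname(g2$final$GS[1]), num1 / den, tolerance = 1e-6)
  expect_equal(unname(g2$final$GS[2]), num2 / den, tolerance = 1e-6)
  # convex-combination bound
  expect_true(all(g2$final$GS >= 0 & g2$final$GS <= 1))
})

test_that("validation error behaves as a mean squared error should", {
  th <- sample_prior(300, seed = 15)
  y <- 2 * th$alpha + th$beta
  fit <- fit_pce_ols(th[1:200, ], y[1:200], build_basis(8, 2))
  err <- validation_mse(fit, th[201:300, ], y[201:300])
  expect_lt(err$mean_mse, 1e-16)           # exactly representable target
  # the zero surrogate scores the output second moment
  fit0 <- fit
  fit0$coefficients[] <- 0
  err0 <- validation_mse(fit0, th[201:300, ], y[201:300])
  expect_equal(err0$mean_mse, mean(y[201:300]^2), tolerance = 1e-12)
  expect_error(validation_mse(fit, th[0, ], y[0]), "empty")
})

test_that("held-out error decreases with degree and training size on a smooth target", {
  f <- function(th) exp(2 * th$alpha) * sin(200 * th$rmin) + th$beta^3
  th <- sample_prior(900, seed = 55)
  y <- f(th)
  val <- sample_prior(200, seed = 56)
  yv <- f(val)
  mse_of <- function(n_train, K) {
    fit <- suppressWarnings(fit_pce_ols(th[1:n_train, ], y[1:n_train],
                                        build_basis(8, K)))
    validation_mse(fit, val, yv)$mean_mse
  }
  m2 <- mse_of(900, 2); m3 <- mse_of(900, 3); m4 <- mse_of(900, 4)
  expect_lt(m3, m2)
  expect_lt(m4, m3)
  expect_lt(mse_of(900, 3), mse_of(400, 3))
})
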