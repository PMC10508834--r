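test_that("root spectra are exact discrete transforms", {
  sol <- coarse_solution()
  sp <- root_spectra(sol, 1)
  art <- sol$fields[[sol$beds[[1]]$artery]]
  pA <- art$p[nrow(art$p), ]
  # mean recovered at omega = 0
  expect_equal(Re(sp$P_rootA[1]), mean(pA), tolerance = 1e-12)
  # Parseval: time-domain variance equals two-sided spectral power
  power <- 2 * sum(Mod(sp$P_rootA[-1])^2) -
    Mod(sp$P_rootA[length(sp$P_rootA)])^2
  expect_equal(var(pA) * (length(pA) - 1) / length(pA), power,
               tolerance = 1e-10)
  # pure harmonic round trip
  n <- sol$grid$n
  x <- 3 * cos(2 * pi * (0:(n - 1)) / n + 0.4)
  X <- (fft(x) / n)[1:(n %/% 2 + 1)]
  expect_equal(Mod(X[2]), 1.5, tolerance = 1e-12)
  expect_lt(max(Mod(X[-2])), 1e-12)
})

test_that("each marched branch obeys the Poiseuille drop at zero frequency", {
  # at omega = 0 every structured-tree branch must satisfy
  # P(0) - P(L) = 8 mu L Q / (pi r^4) with its own radius-dependent viscosity
  net <- make_toy_network(1)
  th <- default_theta()
  th[["rmin"]] <- 1e-2
  num <- coarse_numerics()
  num$keep_cache <- TRUE
  sol <- simulate_network(net, th, default_waveforms(), num)
  prof <- propagate_pathway(sol, 1, "alpha")
  blood <- blood_properties()
  art <- prof[prof$segment == "artery", ]
  mu <- viscosity_law(art$radius_cm, blood)
  drop <- mmHg_to_cgs(art$mean_p_in_mmHg - art$mean_p_out_mmHg)
  pois <- 8 * mu * art$length_cm * art$mean_q / (pi * art$radius_cm^4)
  expect_equal(drop, pois, tolerance = 1e-6)
})

test_that("pathway profiles are continuous, monotone and mass-consistent", {
  sol <- coarse_solution()
  for (side in c("alpha", "beta")) {
    prof <- propagate_pathway(sol, 1, side)
    # pressure continuity across branch interfaces
    expect_equal(prof$mean_p_out_mmHg[-nrow(prof)], prof$mean_p_in_mmHg[-1],
                 tolerance = 1e-10)
    # strictly decreasing mean pressure along the pathway (mean flow > 0)
    expect_true(all(prof$mean_q > 0))
    expect_true(all(diff(prof$mean_p_mmHg) < 0))
    # per-branch steady mass balance at omega = 0
    expect_equal(prof$mean_q, prof$mean_q_out, tolerance = 1e-10)
  }
})

test_that("the pathway root flow matches the proximal coupling flow", {
  sol <- coarse_solution()
  for (b in c(1, 4, 8)) {
    prof <- propagate_pathway(sol, b, "alpha")
    tr <- vessel_trace(sol, sol$beds[[b]]$artery, "outlet")
    expect_equal(prof$mean_q[1], mean(tr$q), tolerance = 5e-3 * abs(mean(tr$q)) + 1e-8)
    # and the venous-root return flow matches the paired vein inlet
    trv <- vessel_trace(sol, sol$beds[[b]]$vein, "inlet")
    expect_equal(prof$mean_q[nrow(prof)], mean(trv$q),
                 tolerance = 5e-3 * abs(mean(trv$q)) + 1e-8)
  }
})

test_that("alpha pathways have at least as many branches as beta pathways", {
  sol <- coarse_solution()
  for (b in seq_len(8)) {
    na <- nrow(propagate_pathway(sol, b, "alpha"))
    nb <- nrow(propagate_pathway(sol, b, "beta"))
    expect_gte(na, nb)
  }
})

test_that("beta-pathway terminal wall shear exceeds the alpha pathway's", {
  sol <- coarse_solution()
  for (b in c(1, 5)) {
    pa <- propagate_pathway(sol, b, "alpha")
    pb <- propagate_pathway(sol, b, "beta")
    wa <- pa$wss[pa$segment == "artery"]
    wb <- pb$wss[pb$segment == "artery"]
    expect_gte(utils::tail(wb, 1), utils::tail(wa, 1))
  }
})

test_that("distal point quantities evaluate the stated formulas", {
  expect_equal(distal_wss(0.001, 0.01, 0.03), 4 * 0.03 * 0.001 / (pi * 1e-6))
  expect_equal(distal_wss(0.001, 0.01, 0.03), 38.197, tolerance = 1e-4)
  expect_equal(distal_wss(0, 0.01, 0.03), 0)
  expect_error(distal_wss(0.001, 0, 0.03), "positive")
})

test_that("distal cyclic stretch vanishes for a steady pressure", {
  expect_equal(cyclic_stretch(rep(1.3, 32)), 0)
  # missing caches give an actionable error
  sol_nc <- simulate_network(make_toy_network(1), default_theta(),
                             default_waveforms(), coarse_numerics())
  expect_error(propagate_pathway(sol_nc, 1, "alpha"), "keep_cache")
})
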