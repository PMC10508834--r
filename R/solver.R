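#' Elastic wall law: pressure from area and its inverse
#'
#' Thin-walled linearly elastic tube law
#' `p(A) = (4/3) K (sqrt(A/A0) - 1)` with stiffness `K = E h / r0` and
#' reference area `A0`; `wall_area()` is its exact inverse
#' `A(p) = A0 (1 + 3 p / (4 K))^2`, valid above the collapse pressure
#' `p > -(4/3) K`.
#'
#' @param A Cross-sectional area cm^2 (vectorised).
#' @param p Transmural pressure g/cm/s^2 (vectorised).
#' @param K Wall stiffness `Eh/r0` in g/cm/s^2.
#' @param A0 Reference area cm^2.
#' @return Pressure (g/cm/s^2) or area (cm^2).
#' @export
#' @examples
#' wall_pressure(4 * pi, K = 8e5, A0 = pi)  # (4/3) K
wall_pressure <- function(A, K, A0) {
  if (any(A <= 0)) abort("area must be positive")
  (4 / 3) * K * (sqrt(A / A0) - 1)
}

#' @rdname wall_pressure
#' @export
wall_area <- function(p, K, A0) {
  f <- (4 / 3) * K
  if (any(p <= -f)) abort("pressure at or below the collapse limit -(4/3)K")
  A0 * (1 + p / f)^2
}

#' Solver numerics configuration
#'
#' @param n_time Storage samples per period; also the frequency-grid length
#'   used for the bed coupling kernels (even, default 1024).
#' @param dx_max Maximum spatial step, cm.
#' @param min_divisions Minimum number of spatial divisions per vessel.
#' @param cfl Target Courant number used to pick the sub-time-step.
#' @param tol_periodic Cycle-to-cycle relative change defining periodic
#'   convergence.
#' @param max_cycles Cap on simulated cardiac cycles.
#' @param viscosity_mode `"radius"` or `"constant"` for the structured trees.
#' @param keep_cache Retain bed admittance caches in the solution for distal
#'   back-substitution.
#' @return A list of class `solver_numerics`.
#' @export
solver_numerics <- function(n_time = 1024, dx_max = 0.25, min_divisions = 9,
                            cfl = 0.5, tol_periodic = 1e-3, max_cycles = 30,
                            viscosity_mode = "radius", keep_cache = FALSE) {
  structure(
    list(n_time = as.integer(n_time), dx_max = dx_max,
         min_divisions = as.integer(min_divisions), cfl = cfl,
         tol_periodic = tol_periodic, max_cycles = as.integer(max_cycles),
         viscosity_mode = viscosity_mode, keep_cache = keep_cache),
    class = "solver_numerics"
  )
}

#' Coarse numerics for surrogate-training simulations
#'
#' A reduced-resolution configuration (256 samples per period, coarser grid)
#' used for the many model evaluations of the uncertainty-quantification
#' study; the methods vignette reports the resolution trade-off.
#' @export
coarse_numerics <- function() {
  solver_numerics(n_time = 256, dx_max = 0.6, min_divisions = 4, cfl = 0.75,
                  tol_periodic = 1e-3, max_cycles = 25)
}

## internal: band-limited periodic resampling of uniform samples to length n
resample_periodic <- function(x, n) {
  m <- length(x)
  if (m == n) return(x)
  X <- fft(x) / m
  Y <- complex(n)
  kmax <- min(m, n) %/% 2
  Y[1] <- X[1]
  if (kmax >= 1) {
    ks <- seq_len(kmax - 1)
    Y[1 + ks] <- X[1 + ks]
    Y[n + 1 - ks] <- X[m + 1 - ks]
    Y[1 + kmax] <- if (2 * kmax == m) Re(X[1 + kmax]) else X[1 + kmax]
    if (2 * kmax < n) Y[n + 1 - kmax] <- Conj(Y[1 + kmax])
  }
  Re(fft(Y, inverse = TRUE))
}

## internal: waveform input (vector of uniform samples, or data frame t/value)
## -> uniform samples of length n over one period
canonical_waveform <- function(w, period, n, what = "waveform") {
  if (is.data.frame(w)) {
    cols <- names(w)
    tcol <- cols[1]; vcol <- cols[2]
    t <- w[[tcol]]; val <- w[[vcol]]
    if (any(t < 0) || any(t > period + 1e-9)) {
      abort(paste0(what, " times must lie within [0, period]"))
    }
    tt <- c(t - period, t, t + period)
    vv <- c(val, val, val)
    tout <- (0:(n - 1)) * period / n
    approx(tt, vv, xout = tout, ties = "ordered")$y
  } else if (is.numeric(w)) {
    resample_periodic(w, n)
  } else {
    abort(paste0(what, " must be a numeric vector or a (t, value) data frame"))
  }
}

#' Boundary waveforms for one cardiac cycle
#'
#' Bundles the prescribed inlet flow `q_MPA(t)` (cm^3/s) and left-atrial
#' pressure `p_LA(t)` (g/cm/s^2), both strictly T-periodic. Inputs may be
#' uniform sample vectors over one period or two-column (t, value) data
#' frames; they are resampled to the solver grid by band-limited (Fourier) or
#' periodic linear interpolation respectively.
#'
#' @param period Cardiac period, s.
#' @param inflow Inlet flow waveform.
#' @param la_pressure Left-atrial pressure waveform (CGS units).
#' @return A list of class `boundary_waveforms`.
#' @export
#' @examples
#' bw <- default_waveforms()
#' bw$period
boundary_waveforms <- function(period, inflow, la_pressure) {
  structure(
    list(period = period, inflow = inflow, la_pressure = la_pressure),
    class = "boundary_waveforms"
  )
}

#' @rdname boundary_waveforms
#' @param n Samples used when generating the default synthetic waveforms.
#' @export
default_waveforms <- function(period = 0.85, n = 1024) {
  qw <- make_inflow(inflow_spec(period = period), n = n)
  pw <- make_la_pressure(la_pressure_spec(period = period), n = n)
  boundary_waveforms(period, qw, pw)
}

## internal: spatial discretization of a network
discretize_network <- function(network, numerics) {
  v <- network$vessels
  ndiv <- pmax(numerics$min_divisions, ceiling(v$length_cm / numerics$dx_max))
  tibble(
    name = v$name, kind = v$kind,
    nx = as.integer(ndiv + 1), dx = v$length_cm / ndiv,
    L = v$length_cm, radius = v$radius_cm, A0 = v$A0_cm2
  )
}

## internal: build the per-bed grand admittances and coupling kernels
build_bed_coupling <- function(network, theta, grid, blood, viscosity_mode,
                               keep_cache) {
  v <- network$vessels
  radius_of <- setNames(v$radius_cm, v$name)
  beds <- network$beds
  lapply(seq_len(nrow(beds)), function(b) {
    ra <- radius_of[[beds$artery[b]]]
    rv <- radius_of[[beds$vein[b]]]
    at <- generate_tree(ra, theta[["alpha"]], theta[["beta"]],
                        theta[["lrrA"]], theta[["rmin"]])
    vt <- mirror_tree(at, rv, theta[["lrrV"]])
    Y <- grand_admittance(at, vt, theta[["K_ST"]], grid, blood,
                          viscosity_mode, keep_cache = keep_cache)
    kern <- admittance_to_time_domain(Y)
    list(artery = beds$artery[b], vein = beds$vein[b], Y = Y, kernels = kern)
  })
}

#' Simulate the proximal network to periodic steady state
#'
#' Runs the nonlinear 1D mass/momentum system with the elastic wall law on
#' every proximal vessel using the two-step Lax-Wendroff scheme: prescribed
#' inlet flow at the main pulmonary artery, conservation of flow and pressure
#' continuity at junctions, grand-admittance convolution coupling at the
#' microvascular beds, and the left-atrial pressure at the vein roots.
#' Successive cardiac cycles are computed until the maximum relative
#' cycle-to-cycle change of midvessel pressure and flow drops below
#' `tol_periodic` (capped at `max_cycles`; a non-periodic result is returned
#' flagged, not dropped).
#'
#' @param network A `proximal_network`.
#' @param theta Named parameter vector (see [theta_bounds()]).
#' @param waveforms A [boundary_waveforms()] object.
#' @param numerics A [solver_numerics()] configuration.
#' @param blood A [blood_properties()] object.
#' @return An object of class `proximal_solution`.
#' @export
#' @examples
#' \donttest{
#' net <- build_proximal_network(pulmonary_vessel_table())
#' sol <- simulate_network(net, default_theta(), default_waveforms(),
#'                         coarse_numerics())
#' flow_balance(sol)
#' }
simulate_network <- function(network, theta = default_theta(),
                             waveforms = default_waveforms(),
                             numerics = solver_numerics(),
                             blood = blood_properties()) {
  stopifnot(inherits(network, "proximal_network"))
  theta <- validate_theta(theta)
  period <- waveforms$period
  grid <- frequency_grid(period, numerics$n_time)

  disc <- discretize_network(network, numerics)
  v <- network$vessels
  K <- ifelse(disc$kind == "artery", theta[["K_A"]], theta[["K_V"]])
  f <- (4 / 3) * K
  c0 <- sqrt(f / (2 * blood$rho))

  beds <- build_bed_coupling(network, theta, grid, blood,
                             numerics$viscosity_mode, numerics$keep_cache)

  idx <- setNames(seq_len(nrow(disc)) - 1L, disc$name)  # 0-based for C++
  jn <- network$junctions
  jdiv <- jn[jn$type == "diverging", , drop = FALSE]
  jconv <- jn[jn$type == "converging", , drop = FALSE]
  jdiv_m <- cbind(idx[jdiv$parent], idx[jdiv$d1], idx[jdiv$d2])
  jconv_m <- cbind(idx[jconv$d1], idx[jconv$d2], idx[jconv$parent])
  storage.mode(jdiv_m) <- "integer"; storage.mode(jconv_m) <- "integer"
  if (nrow(jdiv) == 0) jdiv_m <- matrix(integer(0), 0, 3)
  if (nrow(jconv) == 0) jconv_m <- matrix(integer(0), 0, 3)
  bed_m <- cbind(idx[vapply(beds, `[[`, "", "artery")],
                 idx[vapply(beds, `[[`, "", "vein")])
  storage.mode(bed_m) <- "integer"
  kernels <- lapply(beds, function(b)
    cbind(b$kernels$y11, b$kernels$y12, b$kernels$y21, b$kernels$y22))

  # sub-time-step from the target Courant number with headroom; the compiled
  # core re-checks the actual CFL every step and aborts past 1
  c_est <- max(c0) * 1.12 + 150
  dt_store <- period / numerics$n_time
  substeps <- max(1L, as.integer(ceiling(dt_store * c_est /
                                           (numerics$cfl * min(disc$dx)))))
  qin <- canonical_waveform(waveforms$inflow, period,
                            numerics$n_time * substeps, "inflow")
  pla <- canonical_waveform(waveforms$la_pressure, period,
                            numerics$n_time * substeps, "la_pressure")

  run <- lw_run(
    vessels = list(nx = disc$nx, dx = disc$dx, A0 = disc$A0, f = f, L = disc$L),
    topo = list(inlet = idx[[network$root_artery]], jdiv = jdiv_m,
                jconv = jconv_m,
                vein_out = as.integer(idx[network$vein_roots]),
                nonrefl_out = integer(0), bed_idx = bed_m, kernels = kernels),
    bcs = list(q_inlet = qin, p_la = pla),
    numerics = list(pars = c(blood$rho, blood$nu, blood$gamma, period,
                             0, numerics$n_time, substeps,
                             numerics$max_cycles, numerics$tol_periodic, 1.0))
  )
  if (nzchar(run$error)) {
    abort(paste0("solver failed: ", run$error))
  }
  if (!run$converged) {
    warn(sprintf("simulation not periodic after %d cycles (last change %.3g)",
                 run$cycles, utils::tail(run$conv_history, 1)))
  }

  off <- cumsum(c(0, disc$nx))[seq_len(nrow(disc))]
  fields <- lapply(seq_len(nrow(disc)), function(i) {
    rows <- off[i] + seq_len(disc$nx[i])
    Af <- run$A[rows, , drop = FALSE]
    qf <- run$q[rows, , drop = FALSE]
    list(A = Af, q = qf, p = wall_pressure(Af, K[i], disc$A0[i]))
  })
  names(fields) <- disc$name

  structure(
    list(network = network, disc = disc, theta = theta, grid = grid,
         t = (0:(numerics$n_time - 1)) * dt_store,
         fields = fields, K = setNames(K, disc$name),
         beds = beds, blood = blood, numerics = numerics,
         waveforms = list(q_inlet = qin[(0:(numerics$n_time - 1)) * substeps + 1],
                          p_la = pla[(0:(numerics$n_time - 1)) * substeps + 1]),
         converged = run$converged, cycles = run$cycles,
         conv_history = run$conv_history, cfl_max = run$cfl_max,
         substeps = substeps),
    class = "proximal_solution"
  )
}

#' @export
print.proximal_solution <- function(x, ...) {
  cat(sprintf(paste0("<proximal_solution> %d vessels, %d samples/period, ",
                     "%d cycles (%s), CFL max %.2f\n"),
              nrow(x$disc), x$grid$n, x$cycles,
              if (x$converged) "periodic" else "NOT periodic", x$cfl_max))
  invisible(x)
}

#' Extract a time trace from a solution
#'
#' @param solution A `proximal_solution`.
#' @param vessel Vessel name.
#' @param x `"mid"`, `"inlet"`, `"outlet"`, or a node index.
#' @return Tibble with `t`, `p` (g/cm/s^2), `p_mmHg`, `q`, `A`, `u`, `r`.
#' @export
vessel_trace <- function(solution, vessel, x = "mid") {
  stopifnot(inherits(solution, "proximal_solution"))
  fl <- solution$fields[[vessel]]
  if (is.null(fl)) abort(paste0("unknown vessel: ", vessel))
  nx <- nrow(fl$A)
  j <- switch(as.character(x), mid = nx %/% 2 + 1L, inlet = 1L, outlet = nx,
              as.integer(x))
  tibble(
    t = solution$t,
    p = fl$p[j, ], p_mmHg = cgs_to_mmHg(fl$p[j, ]),
    q = fl$q[j, ], A = fl$A[j, ],
    u = fl$q[j, ] / fl$A[j, ], r = sqrt(fl$A[j, ] / pi)
  )
}

#' @export
tidy.proximal_solution <- function(x, location = "mid", ...) {
  purrr::map_dfr(x$disc$name, function(nm) {
    dplyr::mutate(vessel_trace(x, nm, location), vessel = nm, .before = 1)
  })
}

#' @export
glance.proximal_solution <- function(x, ...) {
  fb <- flow_balance(x)
  mpa <- vessel_trace(x, x$network$root_artery)
  tibble(
    converged = x$converged, cycles = x$cycles, cfl_max = x$cfl_max,
    mean_p_mpa_mmHg = mean(mpa$p_mmHg), sys_p_mpa_mmHg = max(mpa$p_mmHg),
    dia_p_mpa_mmHg = min(mpa$p_mmHg),
    inflow_mean = fb$inflow_mean, outflow_mean = fb$outflow_mean,
    flow_balance_rel = fb$rel_error
  )
}

#' Global mass balance of a converged solution
#'
#' Compares the cycle-averaged prescribed inflow with the summed
#' cycle-averaged outflow at the four vein roots.
#'
#' @param solution A `proximal_solution`.
#' @return List with `inflow_mean`, `outflow_mean`, `rel_error`.
#' @export
flow_balance <- function(solution) {
  inflow <- mean(solution$waveforms$q_inlet)
  outflow <- sum(vapply(solution$network$vein_roots, function(nm) {
    fl <- solution$fields[[nm]]
    mean(fl$q[nrow(fl$q), ])
  }, numeric(1)))
  list(inflow_mean = inflow, outflow_mean = outflow,
       rel_error = abs(inflow - outflow) / abs(inflow))
}

#' Simulate a single vessel (test and verification harness)
#'
#' Runs one vessel with a prescribed inlet flow and either a non-reflecting
#' or a prescribed-pressure outlet. Used for wave-speed, conservation and
#' grid-refinement checks.
#'
#' @param length,radius Geometry (cm).
#' @param K Wall stiffness g/cm/s^2.
#' @param inflow Numeric samples of q(t) over one period, cm^3/s.
#' @param period s.
#' @param outlet `"nonreflecting"` or `"pressure"`.
#' @param p_out Outlet pressure (g/cm/s^2) when `outlet = "pressure"`.
#' @param numerics A [solver_numerics()].
#' @param blood [blood_properties()].
#' @return A `proximal_solution`-like list with a single vessel `"V1"`.
#' @export
simulate_single_vessel <- function(length, radius, K, inflow, period,
                                   outlet = c("nonreflecting", "pressure"),
                                   p_out = 0,
                                   numerics = solver_numerics(max_cycles = 8),
                                   blood = blood_properties()) {
  outlet <- match.arg(outlet)
  ndiv <- max(numerics$min_divisions, ceiling(length / numerics$dx_max))
  nx <- as.integer(ndiv + 1)
  dx <- length / ndiv
  A0 <- pi * radius^2
  f <- (4 / 3) * K
  c0 <- sqrt(f / (2 * blood$rho))
  dt_store <- period / numerics$n_time
  substeps <- max(1L, as.integer(ceiling(dt_store * (c0 * 1.2 + 200) /
                                           (numerics$cfl * dx))))
  qin <- canonical_waveform(inflow, period, numerics$n_time * substeps, "inflow")
  pla <- rep(p_out, numerics$n_time * substeps)
  empty3 <- matrix(integer(0), 0, 3)
  run <- lw_run(
    vessels = list(nx = nx, dx = dx, A0 = A0, f = f, L = length),
    topo = list(inlet = 0L, jdiv = empty3, jconv = empty3,
                vein_out = if (outlet == "pressure") 0L else integer(0),
                nonrefl_out = if (outlet == "nonreflecting") 0L else integer(0),
                bed_idx = matrix(integer(0), 0, 2), kernels = list()),
    bcs = list(q_inlet = qin, p_la = pla),
    numerics = list(pars = c(blood$rho, blood$nu, blood$gamma, period,
                             0, numerics$n_time, substeps,
                             numerics$max_cycles, numerics$tol_periodic, 1.0))
  )
  if (nzchar(run$error)) abort(paste0("solver failed: ", run$error))
  A <- run$A; q <- run$q
  structure(
    list(disc = tibble(name = "V1", kind = "artery", nx = nx, dx = dx,
                       L = length, radius = radius, A0 = A0),
         theta = NULL, grid = frequency_grid(period, numerics$n_time),
         t = (0:(numerics$n_time - 1)) * dt_store,
         fields = list(V1 = list(A = A, q = q, p = wall_pressure(A, K, A0))),
         K = c(V1 = K), beds = list(), blood = blood, numerics = numerics,
         waveforms = list(q_inlet = qin[(0:(numerics$n_time - 1)) * substeps + 1],
                          p_la = pla[(0:(numerics$n_time - 1)) * substeps + 1]),
         converged = run$converged, cycles = run$cycles,
         conv_history = run$conv_history, cfl_max = run$cfl_max,
         substeps = substeps,
         network = list(root_artery = "V1", vein_roots = character(0))),
    class = "proximal_solution"
  )
}
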