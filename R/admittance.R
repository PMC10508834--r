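#' Frequency grid for one cardiac cycle
#'
#' Uniform angular-frequency grid `omega_k = 2 pi k / T`, `k = 0 ... n/2`,
#' matching an `n`-point sampling of one period. The one-sided spectrum is
#' extended by conjugate symmetry when real time-domain kernels are needed.
#'
#' @param period Cardiac period T in s.
#' @param n_samples Even number of time samples per period (default 1024).
#' @return A list of class `frequency_grid` with `period`, `n`, `k`, `omega`,
#'   `dt`.
#' @export
#' @examples
#' frequency_grid(0.85, 256)
frequency_grid <- function(period, n_samples = 1024) {
  if (period <= 0) abort("period must be positive")
  n_samples <- as.integer(n_samples)
  if (n_samples < 4 || n_samples %% 2 != 0) {
    abort("n_samples must be an even integer >= 4")
  }
  k <- 0:(n_samples %/% 2)
  structure(
    list(period = period, n = n_samples, k = k,
         omega = 2 * pi * k / period, dt = period / n_samples),
    class = "frequency_grid"
  )
}

#' Womersley velocity-profile factor
#'
#' The frequency-dependent factor `F = 1 - 2 J1(w0) / (w0 J0(w0))` with
#' `w0 = sqrt(i^3 r^2 omega rho / mu)` that multiplies the inviscid
#' admittance of an oscillatory laminar tube flow. At `omega = 0` the exact
#' small-argument limit `F -> -w0^2/8` is taken analytically, which reduces the
#' vessel admittance to the Poiseuille conductance.
#'
#' @param omega Angular frequency rad/s (vectorised, `>= 0`).
#' @param r Vessel radius cm.
#' @param blood A [blood_properties()] object (supplies the density).
#' @param mu Local dynamic viscosity g/cm/s (defaults to the bulk value).
#' @return Complex vector of the same length as `omega`.
#' @export
womersley_factor <- function(omega, r, blood = blood_properties(),
                             mu = blood$mu) {
  if (r <= 0 || mu <= 0) abort("radius and viscosity must be positive")
  if (any(omega < 0)) abort("omega must be nonnegative")
  out <- complex(length(omega))
  w0sq <- complex(real = 0, imaginary = -1) * r^2 * omega * blood$rho / mu
  small <- Mod(w0sq) < 1e-6
  # series: F = -w0^2/8 * (1 + w0^2/24 + O(w0^4))
  out[small] <- -w0sq[small] / 8 * (1 + w0sq[small] / 24)
  if (any(!small)) {
    w0 <- sqrt(w0sq[!small])
    ratio <- bessel_j_ratio(w0)  # J1(w0)/J0(w0), compiled backward recurrence
    out[!small] <- 1 - 2 * ratio / w0
  }
  out
}

## numerically safe cot(z) and csc(z) for complex z of either half-plane
cot_csc <- function(z) {
  y <- Im(z)
  w <- ifelse(y >= 0, exp(2i * z), exp(-2i * z))
  ez <- ifelse(y >= 0, exp(1i * z), exp(-1i * z))
  den <- ifelse(y >= 0, w - 1, 1 - w)
  bad <- Mod(den) < 1e-14
  if (any(bad)) den[bad] <- den[bad] + 1e-14  # off-grid resonance guard
  cot <- ifelse(y >= 0, 1i * (w + 1), 1i * (1 + w)) / den
  csc <- 2i * ez / den
  list(cot = cot, csc = csc)
}

#' Two-port admittance spectrum of a single distal vessel
#'
#' Frequency-domain 2x2 admittance of one structured-tree branch relating the
#' port flows (both directed into the vessel) to the port pressures:
#' `Y11 = Y22 = -i g cot(omega L / c)`, `Y12 = Y21 = i g csc(omega L / c)`,
#' with line admittance `g = sqrt(C (pi r^2 / rho) F)`, wall compliance per
#' length `C = (3/2) pi r^2 / K_ST`, Womersley factor `F`, and wave speed
#' `c = g / C`. At `omega = 0` the matrix reduces to the Poiseuille form
#' `pi r^4 / (8 mu L) * [[1, -1], [-1, 1]]`. Frequencies where
#' `sin(omega L / c)` would vanish are evaluated through a scaled-exponential
#' (transfer-matrix equivalent) form and stay finite.
#'
#' @param radius,length Vessel geometry in cm.
#' @param K_ST Wall stiffness `Eh/r0` of the structured tree, g/cm/s^2.
#' @param grid A [frequency_grid()].
#' @param blood A [blood_properties()] object.
#' @param viscosity_mode Passed to [viscosity_law()].
#' @return An object of class `admittance_spectrum`: list with complex vectors
#'   `y11`, `y12`, `y21`, `y22` over `grid$omega` and auxiliary per-frequency
#'   scalars `g`, `c`, plus `C`, `mu`, and the grid.
#' @export
vessel_admittance <- function(radius, length, K_ST, grid,
                              blood = blood_properties(),
                              viscosity_mode = "radius") {
  if (radius <= 0 || length <= 0 || K_ST <= 0) {
    abort("radius, length, K_ST must be positive")
  }
  mu <- viscosity_law(radius, blood, viscosity_mode)
  Fw <- womersley_factor(grid$omega, radius, blood, mu)
  Cc <- 1.5 * pi * radius^2 / K_ST
  area <- pi * radius^2
  g <- sqrt(Cc * (area / blood$rho) * Fw)
  cw <- g / Cc
  y11 <- y12 <- complex(length(grid$omega))
  # omega = 0: Poiseuille conductance
  G0 <- pi * radius^4 / (8 * mu * length)
  y11[1] <- G0
  y12[1] <- -G0
  if (length(grid$omega) > 1) {
    idx <- -1
    z <- grid$omega[idx] * length / cw[idx]
    tr <- cot_csc(z)
    y11[idx] <- -1i * g[idx] * tr$cot
    y12[idx] <- 1i * g[idx] * tr$csc
  }
  structure(
    list(y11 = y11, y12 = y12, y21 = y12, y22 = y11,
         g = g, c = cw, C = Cc, mu = mu, grid = grid,
         meta = list(radius = radius, length = length, K_ST = K_ST)),
    class = "admittance_spectrum"
  )
}

## internal: per-branch segment admittances for a whole tree, batched over
## branches and frequencies. Returns matrices (n_freq x n_branch) y11, y12
## and compliance C, viscosity mu per branch. Identical in exact arithmetic
## to column-wise vessel_admittance() calls (tested).
tree_segment_admittances <- function(tree, K_ST, grid, blood, viscosity_mode) {
  nd <- tree$nodes
  nb <- nrow(nd)
  nf <- length(grid$omega)
  r <- nd$radius_cm
  L <- nd$length_cm
  mu <- viscosity_law(r, blood, viscosity_mode)
  Cc <- 1.5 * pi * r^2 / K_ST
  area <- pi * r^2
  y11 <- y12 <- matrix(complex(1), nf, nb)
  G0 <- pi * r^4 / (8 * mu * L)
  y11[1, ] <- G0
  y12[1, ] <- -G0
  if (nf > 1) {
    om <- grid$omega[-1]
    w0sq <- outer(om, r^2 * blood$rho / mu) * complex(imaginary = -1)
    w0 <- sqrt(w0sq)
    Fw <- 1 - 2 * matrix(bessel_j_ratio(as.vector(w0)), nf - 1, nb) / w0
    g <- sqrt(sweep(Fw, 2, Cc * area / blood$rho, `*`))
    z <- outer(om, L) * sweep(1 / g, 2, Cc, `*`)
    tr <- cot_csc(z)
    y11[-1, ] <- -1i * g * matrix(tr$cot, nf - 1, nb)
    y12[-1, ] <- 1i * g * matrix(tr$csc, nf - 1, nb)
  }
  list(y11 = y11, y12 = y12, C = Cc, mu = mu)
}

#' Grand admittance of a two-sided microvascular bed
#'
#' Composes the 2x2 frequency-domain admittance of an entire structured-tree
#' bed: the arterial tree rooted at a terminal proximal artery, its mirrored
#' venous tree, and the terminal junctions where the two meet at `r_min`. The
#' result relates the flows into the bed at the arterial root and at the
#' venous root to the two root pressures (symmetric into-port convention, so
#' the physical vein flow toward the atrium is minus the second port flow).
#'
#' Interior junction pressures are eliminated by recursive two-port
#' composition over the self-similar `(i, j)` lattice, so each distinct index
#' pair is visited exactly once (memoization over identical subtrees). The
#' per-node elimination maps are retained (optionally) so that interior
#' pressures can be back-substituted exactly by [propagate_pathway()].
#'
#' @param arterial_tree,venous_tree `structured_tree`s sharing one index set
#'   (see [mirror_tree()]).
#' @param K_ST Structured-tree wall stiffness g/cm/s^2.
#' @param grid A [frequency_grid()].
#' @param blood A [blood_properties()] object.
#' @param viscosity_mode Passed to [viscosity_law()].
#' @param keep_cache Retain elimination maps and segment admittances for
#'   pathway back-substitution (default TRUE; the UQ driver switches it off).
#' @return An `admittance_spectrum` with entries `y11 ... y22` over the grid;
#'   if `keep_cache`, a `cache` element holds per-node back-substitution data.
#' @export
grand_admittance <- function(arterial_tree, venous_tree, K_ST, grid,
                             blood = blood_properties(),
                             viscosity_mode = "radius",
                             keep_cache = TRUE) {
  stopifnot(inherits(arterial_tree, "structured_tree"),
            inherits(venous_tree, "structured_tree"))
  nd <- arterial_tree$nodes
  if (nrow(venous_tree$nodes) != nrow(nd)) {
    abort("arterial and venous trees must share one (i, j) index set")
  }
  nf <- length(grid$omega)
  segA <- tree_segment_admittances(arterial_tree, K_ST, grid, blood, viscosity_mode)
  segV <- tree_segment_admittances(venous_tree, K_ST, grid, blood, viscosity_mode)

  nb <- nrow(nd)
  key <- paste(nd$i, nd$j)
  row_of <- setNames(seq_len(nb), key)
  ord <- order(nd$i + nd$j, decreasing = TRUE)  # deepest first

  Y11 <- Y12 <- Y21 <- Y22 <- matrix(complex(1), nf, nb)
  Mmap <- if (keep_cache) vector("list", nb) else NULL

  for (b in ord) {
    s11 <- segA$y11[, b]; s12 <- segA$y12[, b]
    v11 <- segV$y11[, b]; v12 <- segV$y12[, b]
    if (nd$terminal[b]) {
      den <- s11 + v11                       # S22 + V11 at the meeting node
      t1 <- -s12 / den                       # P_m = t1 P_a0 + t2 P_v0
      t2 <- -v12 / den
      Y11[, b] <- s11 + s12 * t1
      Y12[, b] <- s12 * t2
      Y21[, b] <- v12 * t1
      Y22[, b] <- v11 + v12 * t2
      if (keep_cache) Mmap[[b]] <- cbind(m11 = t1, m12 = t2)
    } else {
      d11 <- d12 <- d21 <- d22 <- complex(nf)
      if (nd$has_alpha[b]) {
        da <- row_of[[paste(nd$i[b] + 1L, nd$j[b])]]
        d11 <- d11 + Y11[, da]; d12 <- d12 + Y12[, da]
        d21 <- d21 + Y21[, da]; d22 <- d22 + Y22[, da]
      }
      if (nd$has_beta[b]) {
        db <- row_of[[paste(nd$i[b], nd$j[b] + 1L)]]
        d11 <- d11 + Y11[, db]; d12 <- d12 + Y12[, db]
        d21 <- d21 + Y21[, db]; d22 <- d22 + Y22[, db]
      }
      # eliminate the two interior junction pressures (P_a1, P_v1)
      a11 <- s11 + d11; a12 <- d12
      a21 <- d21;       a22 <- d22 + v11
      det <- a11 * a22 - a12 * a21
      bad <- !is.finite(det) | Mod(det) == 0
      if (any(bad)) {
        abort(paste0("ill-conditioned junction elimination at frequency index ",
                     paste(which(bad) - 1L, collapse = ", ")))
      }
      # M maps [P_a0; P_v0] -> [P_a1; P_v1]
      m11 <- -a22 * s12 / det; m12 <- a12 * v12 / det
      m21 <- a21 * s12 / det;  m22 <- -a11 * v12 / det
      Y11[, b] <- s11 + s12 * m11
      Y12[, b] <- s12 * m12
      Y21[, b] <- v12 * m21
      Y22[, b] <- v11 + v12 * m22
      if (keep_cache) Mmap[[b]] <- cbind(m11 = m11, m12 = m12, m21 = m21, m22 = m22)
    }
  }

  root <- row_of[["0 0"]]
  out <- structure(
    list(y11 = Y11[, root], y12 = Y12[, root],
         y21 = Y21[, root], y22 = Y22[, root],
         grid = grid,
         meta = list(K_ST = K_ST, viscosity_mode = viscosity_mode,
                     n_branches = nb)),
    class = "admittance_spectrum"
  )
  if (keep_cache) {
    out$cache <- list(nodes = nd, row_of = row_of, Mmap = Mmap,
                      segA = segA, segV = segV,
                      arterial_tree = arterial_tree, venous_tree = venous_tree)
  }
  out
}

#' @export
print.admittance_spectrum <- function(x, ...) {
  cat(sprintf("<admittance_spectrum> %d frequencies, Y(0) conductance %.4g cm^3 s^-1 / (g cm^-1 s^-2)\n",
              length(x$grid$omega), Re(x$y11[1])))
  invisible(x)
}

#' @export
tidy.admittance_spectrum <- function(x, ...) {
  tibble(
    k = x$grid$k, omega = x$grid$omega,
    y11 = x$y11, y12 = x$y12, y21 = x$y21, y22 = x$y22
  )
}

#' Periodic time-domain coupling kernels from an admittance spectrum
#'
#' Extends the one-sided spectrum by conjugate symmetry and inverse-transforms
#' it to real, T-periodic kernels sampled on the solver grid. The kernels are
#' normalized so that the discrete circular convolution
#' `q_n = sum_m y_m p_(n-m mod N)` reproduces the frequency-domain products
#' `Y(omega_k) P(omega_k)` exactly for band-limited `p`.
#'
#' @param Y An `admittance_spectrum` (vessel or grand).
#' @return A list of class `coupling_kernels` with real vectors `y11 ... y22`
#'   of length `grid$n` and the grid.
#' @export
admittance_to_time_domain <- function(Y) {
  stopifnot(inherits(Y, "admittance_spectrum"))
  n <- Y$grid$n
  one_sided_to_kernel <- function(yk) {
    stopifnot(length(yk) == n %/% 2 + 1)
    full <- complex(n)
    full[1] <- yk[1]
    full[2:(n %/% 2)] <- yk[2:(n %/% 2)]
    full[n %/% 2 + 1] <- complex(real = Re(yk[n %/% 2 + 1]))  # real Nyquist
    full[(n %/% 2 + 2):n] <- Conj(yk[(n %/% 2):2])
    Re(fft(full, inverse = TRUE)) / n
  }
  structure(
    list(y11 = one_sided_to_kernel(Y$y11), y12 = one_sided_to_kernel(Y$y12),
         y21 = one_sided_to_kernel(Y$y21), y22 = one_sided_to_kernel(Y$y22),
         grid = Y$grid),
    class = "coupling_kernels"
  )
}
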