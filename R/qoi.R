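#' Proximal wall shear stress time series
#'
#' For the power-law axial velocity profile with exponent `gamma`, the wall
#' shear stress is `WSS(t) = mu * Ubar(t) * (gamma + 2) / R(t)` with the
#' cross-sectional mean velocity `Ubar = q/A` and lumen radius
#' `R = sqrt(A/pi)`; `gamma = 9` gives the blunt profile factor 11.
#'
#' @param solution A `proximal_solution`.
#' @param vessel Vessel name.
#' @param x Reporting location (default midpoint).
#' @param blood A [blood_properties()] object.
#' @return Tibble with `t` and `wss` (dyn/cm^2).
#' @export
proximal_wss <- function(solution, vessel, x = "mid",
                         blood = solution$blood) {
  tr <- vessel_trace(solution, vessel, x)
  tibble(t = tr$t, wss = blood$mu * tr$u * (blood$gamma + 2) / tr$r)
}

#' Cyclic stretch of a radius trace
#'
#' `CS = (max R - min R) / min R` over one period; the relative radial wall
#' excursion per cardiac cycle.
#'
#' @param R Positive radius samples covering one period.
#' @return Dimensionless scalar.
#' @export
#' @examples
#' cyclic_stretch(1 + 0.05 * sin(seq(0, 2 * pi, length.out = 64)))
cyclic_stretch <- function(R) {
  if (any(!is.finite(R)) || min(R) <= 0) abort("R must be positive and finite")
  (max(R) - min(R)) / min(R)
}

#' Wave intensity analysis with four-type classification
#'
#' Separates pressure and velocity increments into forward and backward
#' components using the water-hammer relations
#' `dP+- = (dP +- rho c dU) / 2`, `dU+- = +- dP+- / (rho c)`, with the local
#' wave speed from the wall law, `c(t) = sqrt((2K / 3 rho) sqrt(A/A0))`.
#' Wave intensities `dI+- = dP+- dU+-` satisfy `dI+ >= 0 >= dI-` pointwise
#' and are classified by the sign of the pressure increment: forward
#' compression (FCW, `dP+ > 0`), forward decompression/expansion (FDW,
#' `dP+ < 0`), backward compression (BCW, `dP- > 0`) and backward
#' decompression (BDW, `dP- < 0`). Increments are centred periodic
#' differences; cumulative intensities are trapezoidal time integrals.
#'
#' @param p,u,A Periodic samples of pressure (g/cm/s^2), velocity (cm/s) and
#'   area (cm^2) on a common uniform grid covering one period.
#' @param K Wall stiffness g/cm/s^2.
#' @param A0 Reference area cm^2.
#' @param period Period T, s.
#' @param blood A [blood_properties()] object.
#' @param wave_speed `"local"` (time-varying, default) or `"diastolic"`
#'   (frozen at the minimum-area state).
#' @param normalize `"per_sample"` (raw increments, default) or `"per_time"`
#'   (increments divided by the time step, intensity in W/m^2-like units).
#' @return A list of class `wia_result` with the component series and a
#'   `summary` tibble of time-integrated intensities per wave type.
#' @export
wia <- function(p, u, A, K, A0, period, blood = blood_properties(),
                wave_speed = c("local", "diastolic"),
                normalize = c("per_sample", "per_time")) {
  wave_speed <- match.arg(wave_speed)
  normalize <- match.arg(normalize)
  n <- length(p)
  if (length(u) != n || length(A) != n) abort("p, u, A must share a grid")
  if (any(A <= 0)) abort("area must be positive")
  dt <- period / n
  cdiff <- function(x) (dplyr::lead(x, default = x[1]) -
                          dplyr::lag(x, default = x[n])) / 2
  dP <- cdiff(p)
  dU <- cdiff(u)
  cA <- if (wave_speed == "local") A else rep(min(A), n)
  c_t <- sqrt((2 * K / (3 * blood$rho)) * sqrt(cA / A0))
  rc <- blood$rho * c_t
  dPp <- (dP + rc * dU) / 2
  dPm <- (dP - rc * dU) / 2
  dUp <- dPp / rc
  dUm <- -dPm / rc
  if (normalize == "per_time") {
    dPp <- dPp / dt; dPm <- dPm / dt; dUp <- dUp / dt; dUm <- dUm / dt
    dP <- dP / dt; dU <- dU / dt
  }
  dIp <- dPp * dUp
  dIm <- dPm * dUm
  types <- list(
    FCW = dIp * (dPp > 0), FDW = dIp * (dPp < 0),
    BCW = dIm * (dPm > 0), BDW = dIm * (dPm < 0)
  )
  trapz <- function(y) dt * sum(y)  # periodic: all weights equal
  summary <- tibble(
    type = names(types),
    direction = c("forward", "forward", "backward", "backward"),
    cumulative = vapply(types, trapz, numeric(1)),
    peak = vapply(types, function(x) max(abs(x)), numeric(1))
  )
  structure(
    list(t = (0:(n - 1)) * dt, dP = dP, dU = dU,
         dP_plus = dPp, dP_minus = dPm, dU_plus = dUp, dU_minus = dUm,
         dI_plus = dIp, dI_minus = dIm, c = c_t,
         FCW = types$FCW, FDW = types$FDW, BCW = types$BCW, BDW = types$BDW,
         summary = summary, normalize = normalize),
    class = "wia_result"
  )
}

#' @export
print.wia_result <- function(x, ...) {
  cat("<wia_result> cumulative intensities by wave type:\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.wia_result <- function(x, ...) {
  tibble(t = x$t, dI_plus = x$dI_plus, dI_minus = x$dI_minus,
         FCW = x$FCW, FDW = x$FDW, BCW = x$BCW, BDW = x$BDW)
}

#' @export
glance.wia_result <- function(x, ...) {
  tidyr::pivot_wider(x$summary[, c("type", "cumulative")],
                     names_from = "type", values_from = "cumulative")
}

#' Wave intensity analysis of a simulated vessel
#'
#' Convenience wrapper applying [wia()] to a vessel's midpoint traces.
#'
#' @inheritParams proximal_wss
#' @param ... Passed to [wia()].
#' @return A `wia_result`.
#' @export
wia_vessel <- function(solution, vessel, x = "mid", ...) {
  tr <- vessel_trace(solution, vessel, x)
  d <- solution$disc[solution$disc$name == vessel, ]
  wia(tr$p, tr$u, tr$A, K = solution$K[[vessel]], A0 = d$A0,
      period = solution$grid$period, blood = solution$blood, ...)
}

#' Proximal quantities of interest for every vessel
#'
#' Cycle metrics per vessel at the midpoint: mean/systolic/diastolic pressure,
#' mean flow, mean and peak wall shear stress, and cyclic stretch.
#'
#' @param solution A `proximal_solution`.
#' @return A tibble, one row per vessel.
#' @export
proximal_qoi <- function(solution) {
  purrr::map_dfr(solution$disc$name, function(nm) {
    tr <- vessel_trace(solution, nm)
    w <- proximal_wss(solution, nm)
    tibble(
      vessel = nm, kind = solution$disc$kind[solution$disc$name == nm],
      mean_p_mmHg = mean(tr$p_mmHg), sys_p_mmHg = max(tr$p_mmHg),
      dia_p_mmHg = min(tr$p_mmHg), mean_q = mean(tr$q),
      mean_wss = mean(w$wss), peak_wss = max(w$wss),
      cs = cyclic_stretch(tr$r)
    )
  })
}
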