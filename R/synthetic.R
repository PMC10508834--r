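#' Synthetic inlet flow specification
#'
#' Parameters of the synthetic main-pulmonary-artery inflow: a smooth,
#' single-peak systolic ejection pulse with near-zero diastolic flow,
#' emulating an MRI-derived flow waveform. The pulse is synthesised from a
#' raised-cosine ejection shape truncated to `harmonic_cap` Fourier modes, so
#' the result is exactly periodic and band-limited; the zeroth harmonic is set
#' so that one period integrates to `stroke_volume` exactly.
#'
#' @param period Cardiac period T, s (default 0.85).
#' @param stroke_volume cm^3 per beat (default 70).
#' @param systolic_fraction Ejection duration / T (default 0.35).
#' @param diastolic_offset Baseline diastolic flow cm^3/s (default 0).
#' @param harmonic_cap Highest retained harmonic (default 10).
#' @return A list of class `inflow_spec`.
#' @export
inflow_spec <- function(period = 0.85, stroke_volume = 70,
                        systolic_fraction = 0.35, diastolic_offset = 0,
                        harmonic_cap = 10) {
  if (stroke_volume <= 0) abort("stroke_volume must be positive")
  if (systolic_fraction <= 0 || systolic_fraction >= 1) {
    abort("systolic_fraction must be in (0, 1)")
  }
  structure(
    list(period = period, stroke_volume = stroke_volume,
         systolic_fraction = systolic_fraction,
         diastolic_offset = diastolic_offset, harmonic_cap = harmonic_cap),
    class = "inflow_spec"
  )
}

## internal: zero out harmonics above cap in-place (uniform samples)
cap_harmonics <- function(x, cap) {
  n <- length(x)
  X <- fft(x)
  keep <- c(0:cap, (n - cap):(n - 1))
  X[setdiff(0:(n - 1), keep) + 1] <- 0
  Re(fft(X, inverse = TRUE)) / n
}

#' Generate the synthetic inlet flow waveform
#'
#' @param spec An [inflow_spec()].
#' @param n Number of uniform samples over one period.
#' @return Tibble with columns `t` (s) and `q` (cm^3/s).
#' @export
#' @examples
#' qw <- make_inflow(inflow_spec())
#' mean(qw$q) * 0.85  # stroke volume
make_inflow <- function(spec, n = 1024) {
  stopifnot(inherits(spec, "inflow_spec"))
  Tp <- spec$period
  t <- (0:(n - 1)) * Tp / n
  t_ej <- spec$systolic_fraction * Tp
  base <- ifelse(t < t_ej, sin(pi * t / t_ej)^2, 0)
  base <- cap_harmonics(base, spec$harmonic_cap)
  target_mean <- spec$stroke_volume / Tp
  ac_mean <- mean(base)
  q <- spec$diastolic_offset +
    (target_mean - spec$diastolic_offset) / ac_mean * base
  # exact stroke volume: adjust only the zeroth harmonic
  q <- q - mean(q) + target_mean
  tibble(t = t, q = q)
}

#' Synthetic left-atrial pressure specification
#'
#' Parameters of the synthetic left-atrial pressure waveform: a two-peak
#' profile with an a-wave (atrial contraction, late in the cycle), the
#' x-descent, a v-wave (atrial filling against the closed mitral valve) and
#' the y-descent, emulating a lumped-parameter left-heart model output. Peaks
#' are periodic von-Mises-shaped bumps truncated to `harmonic_cap` modes; the
#' time average is pinned to `mean_mmHg` exactly.
#'
#' @param period Cardiac period T, s.
#' @param mean_mmHg Mean left-atrial pressure, mmHg (default 5).
#' @param a_amp_mmHg,v_amp_mmHg Peak amplitudes above baseline, mmHg.
#' @param t_a,t_v Peak times as fractions of T (defaults 0.88 and 0.38).
#' @param width Angular concentration of the bumps (von Mises kappa).
#' @param harmonic_cap Highest retained harmonic (default 12).
#' @return A list of class `la_pressure_spec`.
#' @export
la_pressure_spec <- function(period = 0.85, mean_mmHg = 5,
                             a_amp_mmHg = 2.2, v_amp_mmHg = 1.8,
                             t_a = 0.88, t_v = 0.38, width = 14,
                             harmonic_cap = 12) {
  if (a_amp_mmHg < 0 || v_amp_mmHg < 0) abort("amplitudes must be nonnegative")
  if (t_a < 0 || t_a >= 1 || t_v < 0 || t_v >= 1) {
    abort("peak times must be fractions of the period in [0, 1)")
  }
  if (abs(t_a - t_v) < 0.15 && a_amp_mmHg > 0 && v_amp_mmHg > 0) {
    abort("a-wave and v-wave windows overlap")
  }
  structure(
    list(period = period, mean_mmHg = mean_mmHg, a_amp_mmHg = a_amp_mmHg,
         v_amp_mmHg = v_amp_mmHg, t_a = t_a, t_v = t_v, width = width,
         harmonic_cap = harmonic_cap),
    class = "la_pressure_spec"
  )
}

#' Generate the synthetic left-atrial pressure waveform
#'
#' @param spec An [la_pressure_spec()].
#' @param n Number of uniform samples over one period.
#' @return Tibble with columns `t` (s) and `p` (g/cm/s^2).
#' @export
#' @examples
#' pw <- make_la_pressure(la_pressure_spec())
#' cgs_to_mmHg(mean(pw$p))
make_la_pressure <- function(spec, n = 1024) {
  stopifnot(inherits(spec, "la_pressure_spec"))
  Tp <- spec$period
  t <- (0:(n - 1)) * Tp / n
  bump <- function(t0, kappa) {
    b <- exp(kappa * (cos(2 * pi * (t / Tp - t0)) - 1))
    b / max(b)
  }
  p_mmHg <- spec$a_amp_mmHg * bump(spec$t_a, spec$width) +
    spec$v_amp_mmHg * bump(spec$t_v, spec$width)
  p <- mmHg_to_cgs(p_mmHg)
  p <- cap_harmonics(p, spec$harmonic_cap)
  p <- p - mean(p) + mmHg_to_cgs(spec$mean_mmHg)
  tibble(t = t, p = p)
}

#' Toy proximal networks for fast tests
#'
#' Small symmetric artery/vein networks with valid terminal pairing:
#' `n_generations = 1` gives one artery, one vein and one bed;
#' `n_generations = 2` gives a bifurcating parent on each side (3 arteries,
#' 3 veins, 2 beds).
#'
#' @param n_generations 1 or 2.
#' @return A `proximal_network` (strict vessel counts relaxed).
#' @export
make_toy_network <- function(n_generations = 1) {
  if (!n_generations %in% c(1, 2)) abort("n_generations must be 1 or 2")
  if (n_generations == 1) {
    tab <- tibble(
      name = c("A1", "V1"),
      length_cm = c(3, 3), radius_cm = c(0.5, 0.45),
      kind = c("artery", "vein"),
      parent = c(NA, NA), daughter1 = c(NA, NA), daughter2 = c(NA, NA),
      paired_terminal = c("V1", "A1")
    )
  } else {
    tab <- tibble(
      name = c("A1", "A2", "A3", "V1", "V2", "V3"),
      length_cm = c(3, 2, 2, 3, 2, 2),
      radius_cm = c(0.6, 0.45, 0.45, 0.55, 0.42, 0.42),
      kind = c(rep("artery", 3), rep("vein", 3)),
      parent = c(NA, "A1", "A1", NA, "V1", "V1"),
      daughter1 = c("A2", NA, NA, "V2", NA, NA),
      daughter2 = c("A3", NA, NA, "V3", NA, NA),
      paired_terminal = c(NA, "V2", "V3", NA, "A2", "A3")
    )
  }
  build_proximal_network(tab, strict = FALSE)
}
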