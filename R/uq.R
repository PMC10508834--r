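#' Space-filling samples from the parameter prior
#'
#' Latin-hypercube samples of the eight uncertain parameters, uniform within
#' their prior bounds.
#'
#' @param n_samples Number of samples.
#' @param bounds Bounds tibble as from [theta_bounds()].
#' @param seed Integer seed; the same seed reproduces the sample set exactly.
#' @return Tibble with one column per parameter and `n_samples` rows.
#' @export
#' @examples
#' sample_prior(5, seed = 1)
sample_prior <- function(n_samples, bounds = theta_bounds(), seed = 2023) {
  if (n_samples < 1) abort("n_samples must be >= 1")
  if (any(bounds$lower >= bounds$upper)) {
    abort("invalid bounds: need lower < upper for every parameter")
  }
  u <- withr::with_seed(seed, lhs::randomLHS(n_samples, nrow(bounds)))
  x <- sweep(u, 2, bounds$upper - bounds$lower, `*`)
  x <- sweep(x, 2, bounds$lower, `+`)
  colnames(x) <- bounds$parameter
  as_tibble(x)
}

## internal: multi-indices of total degree <= K over n variables (J x n)
total_degree_indices <- function(n, K) {
  grow <- function(prefix, remaining, budget) {
    if (remaining == 0) return(matrix(prefix, nrow = 1))
    do.call(rbind, lapply(0:budget, function(d) {
      grow(c(prefix, d), remaining - 1, budget - d)
    }))
  }
  idx <- grow(integer(0), n, K)
  idx[order(rowSums(idx)), , drop = FALSE]
}

## internal: Legendre polynomials P_0..P_K at x in [-1, 1], (length(x) x K+1)
legendre_table <- function(x, K) {
  P <- matrix(0, length(x), K + 1)
  P[, 1] <- 1
  if (K >= 1) P[, 2] <- x
  if (K >= 2) {
    for (k in 1:(K - 1)) {
      P[, k + 2] <- ((2 * k + 1) * x * P[, k + 1] - k * P[, k]) / (k + 1)
    }
  }
  P
}

#' Legendre polynomial-chaos basis
#'
#' Tensorized Legendre basis of total degree at most `degree` over `n`
#' parameters, orthogonal under the uniform prior. The number of basis
#' functions is `J = choose(n + degree, degree)`; the normalization factors
#' are `gamma_j = prod_i 1 / (2 k_i + 1)` for multi-index `k`.
#'
#' @param n Number of parameters (8 for the full model).
#' @param degree Total polynomial degree `K >= 1`.
#' @param bounds Bounds tibble mapping each parameter to the standard
#'   interval; defaults to [theta_bounds()] when `n == 8`.
#' @return A list of class `pce_basis` with `indices` (J x n), `gamma` (J),
#'   `evaluate(theta_matrix)` returning the design matrix, and metadata.
#' @export
#' @examples
#' b <- build_basis(8, 4)
#' nrow(b$indices)  # 495
build_basis <- function(n, degree, bounds = NULL) {
  if (degree < 1) abort("degree must be >= 1")
  if (is.null(bounds) && n == 8) bounds <- theta_bounds()
  if (is.null(bounds)) {
    bounds <- tibble(parameter = paste0("x", seq_len(n)),
                     lower = rep(-1, n), upper = rep(1, n))
  }
  if (nrow(bounds) != n) abort("bounds must have one row per parameter")
  indices <- total_degree_indices(n, degree)
  gamma <- apply(indices, 1, function(k) prod(1 / (2 * k + 1)))
  lo <- bounds$lower; up <- bounds$upper
  evaluate <- function(theta) {
    theta <- as.matrix(theta)
    if (ncol(theta) != n) abort("theta has the wrong number of columns")
    xs <- sweep(sweep(theta, 2, lo, `-`), 2, (up - lo) / 2, `/`) - 1
    Psi <- matrix(1, nrow(theta), nrow(indices))
    for (i in seq_len(n)) {
      Ptab <- legendre_table(xs[, i], degree)
      Psi <- Psi * Ptab[, indices[, i] + 1, drop = FALSE]
    }
    Psi
  }
  structure(
    list(n = n, degree = degree, indices = indices, gamma = gamma,
         bounds = bounds, evaluate = evaluate),
    class = "pce_basis"
  )
}

#' Fit a polynomial-chaos surrogate by ordinary least squares
#'
#' Solves the regression problem for the coefficient matrix via a QR
#' decomposition of the design matrix (mathematically the normal-equation
#' solution, numerically stable). Outputs may be a vector (scalar quantity of
#' interest) or a matrix with one column per output coordinate (e.g. time
#' point), sharing one basis.
#'
#' @param theta Training inputs: data frame or matrix, columns in the order of
#'   the basis bounds.
#' @param y Training outputs: length-N vector or N x m matrix.
#' @param basis A [build_basis()] object.
#' @return Object of class `pce_surrogate` with `coefficients` (J x m),
#'   `basis`, and training metadata.
#' @export
fit_pce_ols <- function(theta, y, basis) {
  stopifnot(inherits(basis, "pce_basis"))
  theta <- as.matrix(theta)
  y <- as.matrix(y)
  J <- nrow(basis$indices)
  if (nrow(theta) != nrow(y)) abort("theta and y row counts differ")
  if (nrow(theta) < J) {
    abort(sprintf("need at least J = %d training samples, got %d", J, nrow(theta)))
  }
  if (nrow(theta) < 2 * J) {
    warn(sprintf("training size %d below 2J = %d; coefficients may be noisy",
                 nrow(theta), 2 * J))
  }
  Psi <- basis$evaluate(theta)
  qrd <- qr(Psi)
  if (qrd$rank < J) {
    d <- abs(diag(qr.R(qrd)))
    abort(sprintf("rank-deficient PCE design (rank %d < J = %d, cond ~ %.3g)",
                  qrd$rank, J, max(d) / max(min(d), 1e-300)))
  }
  co <- qr.coef(qrd, y)
  structure(
    list(coefficients = co, basis = basis, n_train = nrow(theta),
         output_names = colnames(y)),
    class = "pce_surrogate"
  )
}

#' @export
predict.pce_surrogate <- function(object, newdata, ...) {
  Psi <- object$basis$evaluate(as.matrix(newdata))
  out <- Psi %*% object$coefficients
  if (ncol(out) == 1) drop(out) else out
}

#' @export
print.pce_surrogate <- function(x, ...) {
  cat(sprintf("<pce_surrogate> degree %d, J = %d basis functions, %d output(s), %d training samples\n",
              x$basis$degree, nrow(x$basis$indices),
              ncol(x$coefficients), x$n_train))
  invisible(x)
}

#' Mean and variance of a fitted surrogate
#'
#' The surrogate mean is the constant-basis coefficient; the variance is
#' `sum_(j>=1) c_j^2 gamma_j` per output coordinate.
#'
#' @param surrogate A `pce_surrogate`.
#' @return Tibble with `coordinate`, `mean`, `variance`, `sd`.
#' @export
surrogate_moments <- function(surrogate) {
  co <- surrogate$coefficients
  gam <- surrogate$basis$gamma
  mu <- co[1, ]
  v <- colSums(co[-1, , drop = FALSE]^2 * gam[-1])
  tibble(coordinate = seq_along(mu), mean = unname(mu),
         variance = unname(v), sd = sqrt(unname(v)))
}

#' @export
glance.pce_surrogate <- function(x, ...) {
  m <- surrogate_moments(x)
  tibble(degree = x$basis$degree, J = nrow(x$basis$indices),
         n_train = x$n_train, n_outputs = nrow(m),
         mean_variance = mean(m$variance))
}

#' Sobol' indices from PCE coefficients
#'
#' First-order indices sum the squared, normalized coefficients of basis
#' functions depending on one parameter only; total-order indices sum those of
#' every basis function involving the parameter.
#'
#' @param surrogate A `pce_surrogate`.
#' @return Object of class `sobol_indices`: list with matrices `S`, `ST`
#'   (parameters x outputs), partial-variance matrices, the per-output
#'   `variance`, and a `zero_variance` flag vector.
#' @export
sobol_from_pce <- function(surrogate) {
  co <- surrogate$coefficients
  idx <- surrogate$basis$indices
  gam <- surrogate$basis$gamma
  n <- surrogate$basis$n
  m <- ncol(co)
  contrib <- co^2 * gam                       # J x m variance contributions
  varz <- colSums(contrib[-1, , drop = FALSE])
  S <- ST <- matrix(0, n, m,
                    dimnames = list(surrogate$basis$bounds$parameter, NULL))
  for (i in seq_len(n)) {
    only_i <- idx[, i] > 0 & rowSums(idx[, -i, drop = FALSE]) == 0
    any_i <- idx[, i] > 0
    S[i, ] <- colSums(contrib[only_i, , drop = FALSE])
    ST[i, ] <- colSums(contrib[any_i, , drop = FALSE])
  }
  # numerically zero variance: below round-off relative to the mean level
  zerovar <- varz <= 1e-20 * pmax(co[1, ]^2, 1)
  Sn <- sweep(S, 2, pmax(varz, .Machine$double.xmin), `/`)
  STn <- sweep(ST, 2, pmax(varz, .Machine$double.xmin), `/`)
  Sn[, zerovar] <- NA_real_
  STn[, zerovar] <- NA_real_
  if (any(zerovar)) warn("zero-variance output: Sobol' indices undefined there")
  structure(
    list(S = Sn, ST = STn, partial_S = S, partial_ST = ST,
         variance = varz, zero_variance = zerovar,
         parameters = surrogate$basis$bounds$parameter),
    class = "sobol_indices"
  )
}

#' @export
tidy.sobol_indices <- function(x, ...) {
  m <- ncol(x$S)
  out <- tibble(
    parameter = rep(x$parameters, m),
    coordinate = rep(seq_len(m), each = length(x$parameters)),
    S = as.vector(x$S), ST = as.vector(x$ST)
  )
  if (m == 1) out$coordinate <- NULL
  out
}

#' @export
print.sobol_indices <- function(x, ...) {
  cat(sprintf("<sobol_indices> %d parameters x %d output(s)\n",
              nrow(x$S), ncol(x$S)))
  if (ncol(x$S) == 1) print(tidy(x))
  invisible(x)
}

#' Generalized (time-integrated) Sobol' indices
#'
#' For a time-series surrogate, the generalized index at time `t_j` is the
#' variance-weighted cumulative average
#' `GS_i(t_j) = int_0^tj S_i Var dt / int_0^tj Var dt` (trapezoidal), and its
#' value at the final time `T` is the scalar measure of parameter importance.
#'
#' @param surrogate A `pce_surrogate` whose output coordinates are successive
#'   time points spanning one period.
#' @param times Optional time vector (defaults to equispaced over the
#'   coordinates).
#' @return Object of class `generalized_sobol`: list with matrices `GS`,
#'   `GST` (parameters x time), `times`, and a `final` tibble of the values
#'   at `T`.
#' @export
generalized_sobol <- function(surrogate, times = NULL) {
  sob <- sobol_from_pce(surrogate)
  m <- ncol(sob$S)
  if (is.null(times)) times <- seq(0, 1, length.out = m)
  if (length(times) != m) abort("times must match output coordinates")
  cumtrapz <- function(y) {
    if (length(y) == 1) return(y)
    c(0, cumsum(diff(times) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
  }
  denom <- cumtrapz(sob$variance)
  if (utils::tail(denom, 1) <= 0) {
    warn("zero cumulative variance: generalized indices undefined")
  }
  gs_one <- function(partial) {
    t(apply(partial, 1, function(di) {
      num <- cumtrapz(di)
      out <- num / denom
      out[denom == 0] <- NA_real_
      out
    }))
  }
  GS <- gs_one(sob$partial_S)
  GST <- gs_one(sob$partial_ST)
  final <- tibble(parameter = sob$parameters,
                  GS = GS[, m], GST = GST[, m])
  structure(
    list(GS = GS, GST = GST, times = times, final = final,
         parameters = sob$parameters),
    class = "generalized_sobol"
  )
}

#' @export
tidy.generalized_sobol <- function(x, ...) x$final

#' @export
print.generalized_sobol <- function(x, ...) {
  cat("<generalized_sobol> final (t = T) values:\n")
  print(dplyr::arrange(x$final, dplyr::desc(.data$GST)))
  invisible(x)
}

#' Held-out validation error of a surrogate
#'
#' Mean squared error over a validation set, per output coordinate and
#' averaged, as the metric of surrogate accuracy.
#'
#' @param surrogate A `pce_surrogate`.
#' @param theta_val,y_val Held-out inputs and outputs.
#' @return List with `mse` (per coordinate) and `mean_mse`.
#' @export
validation_mse <- function(surrogate, theta_val, y_val) {
  y_val <- as.matrix(y_val)
  if (nrow(y_val) == 0) abort("validation set is empty")
  pred <- predict(surrogate, theta_val)
  pred <- as.matrix(pred)
  mse <- colMeans((y_val - pred)^2)
  list(mse = mse, mean_mse = mean(mse))
}

## ---------------------------------------------------------------------------
## full study driver
## ---------------------------------------------------------------------------

## internal: QoIs extracted from one simulation for the UQ study
extract_uq_qoi <- function(sol, nt_out = 64) {
  pick <- round(seq(1, sol$grid$n, length.out = nt_out))
  mpa <- vessel_trace(sol, sol$network$root_artery)
  wssm <- proximal_wss(sol, sol$network$root_artery)
  cs_art <- vapply(c(sol$network$root_artery), function(nm) {
    cyclic_stretch(vessel_trace(sol, nm)$r)
  }, numeric(1))
  cs_vein <- vapply(sol$network$vein_roots, function(nm) {
    cyclic_stretch(vessel_trace(sol, nm)$r)
  }, numeric(1))
  q_vein <- vapply(sol$network$vein_roots, function(nm) {
    mean(vessel_trace(sol, nm, "outlet")$q)
  }, numeric(1))
  list(
    p_mpa = mpa$p[pick] / MMHG,          # mmHg time series
    wss_mpa = wssm$wss[pick],
    cs_mpa = unname(cs_art[1]),
    cs_veins = cs_vein,
    q_veins = q_vein,
    times = sol$t[pick]
  )
}

#' Run the uncertainty-quantification study
#'
#' Samples the parameter prior, simulates the network for every draw
#' (training and validation sets), extracts quantities of interest, fits
#' Legendre PCE surrogates at the requested degrees, and computes validation
#' errors, moments, Sobol' and generalized Sobol' indices. Failed or
#' non-periodic simulations are excluded (hard cap 5% of draws).
#'
#' @param network A `proximal_network`.
#' @param waveforms A [boundary_waveforms()].
#' @param n_train,n_val Training and validation sample counts.
#' @param degrees PCE total degrees to fit (e.g. `c(2, 3)`).
#' @param seed Integer seed for both sample sets.
#' @param numerics Solver configuration (default [coarse_numerics()]).
#' @param nt_out Time points retained per series output.
#' @param progress Print a dot every 25 simulations.
#' @return Object of class `uq_study`.
#' @export
run_uq_study <- function(network, waveforms = default_waveforms(),
                         n_train = 200, n_val = 50, degrees = c(2, 3),
                         seed = 2023, numerics = coarse_numerics(),
                         nt_out = 64, progress = FALSE) {
  samples <- sample_prior(n_train + n_val, seed = seed)
  qois <- vector("list", nrow(samples))
  ok <- logical(nrow(samples))
  for (s in seq_len(nrow(samples))) {
    res <- tryCatch(
      withCallingHandlers(
        simulate_network(network, unlist(samples[s, ]), waveforms, numerics),
        warning = function(w) invokeRestart("muffleWarning")
      ),
      error = function(e) NULL
    )
    if (!is.null(res)) {
      qois[[s]] <- extract_uq_qoi(res, nt_out)
      ok[s] <- TRUE
    }
    if (progress && s %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  n_fail <- sum(!ok)
  if (n_fail > 0.05 * nrow(samples)) {
    abort(sprintf("%d of %d simulations failed (cap 5%%)", n_fail, nrow(samples)))
  }
  is_train <- seq_len(nrow(samples)) <= n_train
  tr <- which(ok & is_train)
  vl <- which(ok & !is_train)

  gather <- function(rows, what) {
    do.call(rbind, lapply(qois[rows], function(q) {
      x <- q[[what]]
      matrix(x, nrow = 1)
    }))
  }
  outputs <- list(
    p_mpa = list(train = gather(tr, "p_mpa"), val = gather(vl, "p_mpa"),
                 times = qois[[tr[1]]]$times, series = TRUE),
    wss_mpa = list(train = gather(tr, "wss_mpa"), val = gather(vl, "wss_mpa"),
                   times = qois[[tr[1]]]$times, series = TRUE),
    cs_mpa = list(train = gather(tr, "cs_mpa"), val = gather(vl, "cs_mpa"),
                  series = FALSE),
    cs_veins = list(train = gather(tr, "cs_veins"), val = gather(vl, "cs_veins"),
                    series = FALSE,
                    names = network$vein_roots),
    q_veins = list(train = gather(tr, "q_veins"), val = gather(vl, "q_veins"),
                   series = FALSE, names = network$vein_roots)
  )

  fits <- lapply(degrees, function(K) {
    basis <- build_basis(8, K)
    lapply(outputs, function(o) {
      sur <- withCallingHandlers(
        fit_pce_ols(samples[tr, ], o$train, basis),
        warning = function(w) invokeRestart("muffleWarning")
      )
      err <- validation_mse(sur, samples[vl, ], o$val)
      list(surrogate = sur, mse = err)
    })
  })
  names(fits) <- paste0("K", degrees)

  structure(
    list(samples = samples, train_rows = tr, val_rows = vl,
         n_failed = n_fail, outputs = outputs, fits = fits,
         degrees = degrees, seed = seed, numerics = numerics),
    class = "uq_study"
  )
}

#' @export
print.uq_study <- function(x, ...) {
  cat(sprintf("<uq_study> %d train + %d val simulations (%d failed), degrees %s\n",
              length(x$train_rows), length(x$val_rows), x$n_failed,
              paste(x$degrees, collapse = ", ")))
  print(glance(x))
  invisible(x)
}

#' @export
glance.uq_study <- function(x, ...) {
  purrr::map_dfr(names(x$fits), function(k) {
    tibble(degree = k,
           qoi = names(x$fits[[k]]),
           mean_mse = vapply(x$fits[[k]], function(f) f$mse$mean_mse,
                             numeric(1)))
  })
}

#' Parameter-importance summary of a study output
#'
#' Generalized Sobol' indices (series outputs) or plain PCE Sobol' indices
#' (scalar outputs) for one quantity of interest at one fitted degree.
#'
#' @param study A `uq_study`.
#' @param qoi Output name (e.g. `"p_mpa"`, `"cs_veins"`).
#' @param degree Degree label or number (defaults to the highest fitted).
#' @param coordinate For multi-column scalar outputs, which column.
#' @return Tibble with `parameter`, `S`, `ST` (generalized values for series).
#' @export
study_sobol <- function(study, qoi, degree = NULL, coordinate = 1) {
  k <- if (is.null(degree)) {
    paste0("K", max(study$degrees))
  } else if (is.numeric(degree)) paste0("K", degree) else degree
  f <- study$fits[[k]][[qoi]]
  if (is.null(f)) abort(paste0("no fitted output: ", qoi, " at ", k))
  o <- study$outputs[[qoi]]
  if (isTRUE(o$series)) {
    gs <- generalized_sobol(f$surrogate, times = o$times)
    dplyr::rename(gs$final, S = "GS", ST = "GST")
  } else {
    sob <- sobol_from_pce(f$surrogate)
    tibble(parameter = sob$parameters,
           S = sob$S[, coordinate], ST = sob$ST[, coordinate])
  }
}
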