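#' Root pressure spectra of a microvascular bed
#'
#' Discrete Fourier coefficients (normalized so `p_n = sum_k P_k exp(i w_k t_n)`)
#' of the terminal-artery outlet pressure and the paired-vein inlet pressure
#' of one bed, on the solution's frequency grid. These drive the distal
#' back-substitution.
#'
#' @param solution A `proximal_solution` run with `keep_cache = TRUE` numerics.
#' @param bed Bed index (1..8) or terminal artery name.
#' @return List with complex one-sided spectra `P_rootA`, `P_rootV`
#'   (k = 0..n/2) and the grid.
#' @export
root_spectra <- function(solution, bed) {
  b <- resolve_bed(solution, bed)
  if (!isTRUE(solution$converged)) {
    warn("solution is not periodic; distal spectra inherit that error")
  }
  art <- solution$fields[[b$artery]]
  ven <- solution$fields[[b$vein]]
  pA <- art$p[nrow(art$p), ]   # artery outlet
  pV <- ven$p[1, ]             # vein inlet
  n <- solution$grid$n
  half <- function(x) (fft(x) / n)[1:(n %/% 2 + 1)]
  list(P_rootA = half(pA), P_rootV = half(pV), grid = solution$grid)
}

resolve_bed <- function(solution, bed) {
  if (is.character(bed)) {
    hit <- which(vapply(solution$beds, `[[`, "", "artery") == bed)
    if (length(hit) != 1) abort(paste0("unknown bed: ", bed))
    bed <- hit
  }
  if (bed < 1 || bed > length(solution$beds)) abort("bed index out of range")
  solution$beds[[bed]]
}

## reconstruct one-sided spectrum -> time samples
spectrum_to_time <- function(P, n) {
  full <- complex(n)
  full[1] <- P[1]
  full[2:(n %/% 2)] <- P[2:(n %/% 2)]
  full[n %/% 2 + 1] <- complex(real = Re(P[n %/% 2 + 1]))
  full[(n %/% 2 + 2):n] <- Conj(P[(n %/% 2):2])
  Re(fft(full, inverse = TRUE))
}

#' Distal hemodynamics along the alpha-only or beta-only pathway
#'
#' Marches the frequency-domain pressure/flow solution from the arterial root
#' of a bed down the major-daughter (`alpha`) or minor-daughter (`beta`)
#' pathway, across the terminal junction where the trees meet, and back up the
#' mirrored venous pathway, using the interior-junction elimination maps
#' cached during the grand-admittance composition. Per branch it reports the
#' mean (zero-frequency) pressure and flow, the Poiseuille mean wall shear
#' stress `4 mu Qbar / (pi Rbar^3)`, and the cyclic stretch reconstructed from
#' the linearized wall compliance `A(t) = A0 + C p(t)`.
#'
#' @param solution A `proximal_solution` with bed caches
#'   (`solver_numerics(keep_cache = TRUE)`).
#' @param bed Bed index or terminal artery name.
#' @param side `"alpha"` or `"beta"`.
#' @return A tibble of class `pathway_profile`: one row per branch from the
#'   arterial root to the venous root, columns `side`, `segment`
#'   (artery/vein), `i`, `j`, `radius_cm`, `length_cm`, `distance_cm`
#'   (from the tree's distal end, negative on the venous side),
#'   `mean_p_mmHg`, `mean_q`, `wss`, `cs`.
#' @export
propagate_pathway <- function(solution, bed, side = c("alpha", "beta")) {
  side <- match.arg(side)
  b <- resolve_bed(solution, bed)
  if (is.null(b$Y$cache)) {
    abort("bed admittance cache missing: re-run simulate_network with solver_numerics(keep_cache = TRUE)")
  }
  sp <- root_spectra(solution, bed)
  cache <- b$Y$cache
  nd <- cache$nodes
  row_of <- cache$row_of
  n <- solution$grid$n

  # walk the (i, j) lattice: follow the requested side while it exists, else
  # the major daughter, until the terminal node
  path <- integer(0)
  cur <- row_of[["0 0"]]
  repeat {
    path <- c(path, cur)
    if (nd$terminal[cur]) break
    nxt <- if (side == "beta" && nd$has_beta[cur]) {
      row_of[[paste(nd$i[cur], nd$j[cur] + 1L)]]
    } else {
      row_of[[paste(nd$i[cur] + 1L, nd$j[cur])]]
    }
    cur <- nxt
  }

  PA <- sp$P_rootA
  PV <- sp$P_rootV
  art_rows <- vector("list", length(path))
  ven_rows <- vector("list", length(path))
  for (d in seq_along(path)) {
    bidx <- path[d]
    M <- cache$Mmap[[bidx]]
    s11 <- cache$segA$y11[, bidx]; s12 <- cache$segA$y12[, bidx]
    v11 <- cache$segV$y11[, bidx]; v12 <- cache$segV$y12[, bidx]
    if (nd$terminal[bidx]) {
      Pm <- M[, "m11"] * PA + M[, "m12"] * PV
      Pa1 <- Pm; Pv1 <- Pm
    } else {
      Pa1 <- M[, "m11"] * PA + M[, "m12"] * PV
      Pv1 <- M[, "m21"] * PA + M[, "m22"] * PV
    }
    # arterial branch: ports (PA -> Pa1); +x flow: inlet = into-port at x=0,
    # outlet = minus into-port at x=L
    Qa0 <- s11 * PA + s12 * Pa1
    QaL <- -(s12 * PA + s11 * Pa1)
    # venous branch: runs v1 -> v0 in the flow direction
    Qv0 <- v11 * Pv1 + v12 * PV
    QvL <- -(v12 * Pv1 + v11 * PV)
    art_rows[[d]] <- branch_row(solution, b, "artery", nd[bidx, ],
                                cache$arterial_tree, cache$segA$C[bidx],
                                cache$segA$mu[bidx], PA, Pa1, Qa0, QaL, n)
    ven_rows[[d]] <- branch_row(solution, b, "vein", nd[bidx, ],
                                cache$venous_tree, cache$segV$C[bidx],
                                cache$segV$mu[bidx], Pv1, PV, Qv0, QvL, n)
    PA <- Pa1
    PV <- Pv1
  }

  prof <- dplyr::bind_rows(
    dplyr::bind_rows(art_rows),
    dplyr::bind_rows(rev(ven_rows))
  )
  prof$side <- side
  # signed distance from the distal end (arterial side positive)
  na <- length(path)
  art_len <- prof$length_cm[seq_len(na)]
  ven_len <- prof$length_cm[na + seq_len(na)]
  prof$distance_cm <- c(rev(cumsum(rev(art_len))) - art_len / 2,
                        -(cumsum(ven_len) - ven_len / 2))
  class(prof) <- c("pathway_profile", class(prof))
  prof
}

branch_row <- function(solution, bed, segment, node, tree, C, mu,
                       P0, PL, Q0, QL, n) {
  radius <- tree$nodes$radius_cm[tree$nodes$i == node$i & tree$nodes$j == node$j]
  length_cm <- tree$nodes$length_cm[tree$nodes$i == node$i & tree$nodes$j == node$j]
  A0 <- pi * radius^2
  Pmid <- (P0 + PL) / 2
  pmid_t <- spectrum_to_time(Pmid, n)
  A_t <- A0 + C * pmid_t
  if (min(A_t) <= 0) A_t <- pmax(A_t, 1e-12)
  R_t <- sqrt(A_t / pi)
  qbar <- Re(Q0[1])
  rbar <- mean(R_t)
  tibble(
    segment = segment, i = node$i, j = node$j,
    radius_cm = radius, length_cm = length_cm,
    mean_p_mmHg = cgs_to_mmHg(Re(Pmid[1])),
    mean_p_in_mmHg = cgs_to_mmHg(Re(P0[1])),
    mean_p_out_mmHg = cgs_to_mmHg(Re(PL[1])),
    mean_q = qbar, mean_q_out = Re(QL[1]),
    wss = distal_wss(qbar, rbar, mu),
    cs = cyclic_stretch(R_t)
  )
}

#' Poiseuille mean wall shear stress of a distal branch
#'
#' `WSS = 4 mu Qbar / (pi Rbar^3)` for the zero-frequency (time-averaged)
#' flow `Qbar` and radius `Rbar`, with the radius-dependent viscosity `mu`.
#'
#' @param qbar Mean flow cm^3/s.
#' @param rbar Mean radius cm.
#' @param mu Dynamic viscosity g/cm/s.
#' @return Shear stress dyn/cm^2.
#' @export
#' @examples
#' distal_wss(0.001, 0.01, 0.03)
distal_wss <- function(qbar, rbar, mu) {
  if (any(rbar <= 0)) abort("mean radius must be positive")
  4 * mu * qbar / (pi * rbar^3)
}

#' Distal quantities of interest of both pathways of every bed
#'
#' @param solution A `proximal_solution` with bed caches.
#' @param beds Bed indices (default all).
#' @return Tibble of pathway profiles with a `bed` column.
#' @export
distal_qoi <- function(solution, beds = seq_along(solution$beds)) {
  purrr::map_dfr(beds, function(b) {
    dplyr::bind_rows(
      dplyr::mutate(propagate_pathway(solution, b, "alpha"), bed = b),
      dplyr::mutate(propagate_pathway(solution, b, "beta"), bed = b)
    )
  })
}
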