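# Independent oracles used across test files.

# High-precision power-series Bessel J_nu for complex z of moderate modulus.
bessel_series <- function(z, nu, terms = 70) {
  s <- 0 + 0i
  for (k in 0:terms) {
    s <- s + (-1)^k * (z / 2)^(2 * k + nu) / (gamma(k + 1) * gamma(k + nu + 1))
  }
  s
}

womersley_series <- function(omega, r, rho, mu) {
  w0 <- sqrt(complex(imaginary = -1) * r^2 * omega * rho / mu)
  1 - 2 * bessel_series(w0, 1) / (w0 * bessel_series(w0, 0))
}

# Direct sparse-network assembly oracle for a two-sided structured-tree bed:
# expands the literal tree (every branch an edge with its 2x2 admittance
# stamp) and Schur-eliminates all interior node pressures, per frequency.
direct_grand_oracle <- function(at, vt, K_ST, grid, viscosity_mode = "constant") {
  blood <- blood_properties()
  nd <- at$nodes
  stopifnot(nd$i[1] == 0, nd$j[1] == 0)
  edges <- list()
  nnode <- 2L  # 1 = arterial port, 2 = venous port
  key <- paste(nd$i, nd$j)
  rec <- function(b, anode, vnode) {
    if (nd$terminal[b]) {
      nnode <<- nnode + 1L
      m <- nnode
      edges[[length(edges) + 1]] <<- list(n1 = anode, n2 = m, side = "a", b = b)
      edges[[length(edges) + 1]] <<- list(n1 = m, n2 = vnode, side = "v", b = b)
    } else {
      nnode <<- nnode + 1L; a2 <- nnode
      nnode <<- nnode + 1L; v2 <- nnode
      edges[[length(edges) + 1]] <<- list(n1 = anode, n2 = a2, side = "a", b = b)
      edges[[length(edges) + 1]] <<- list(n1 = v2, n2 = vnode, side = "v", b = b)
      if (nd$has_alpha[b]) rec(which(key == paste(nd$i[b] + 1, nd$j[b])), a2, v2)
      if (nd$has_beta[b]) rec(which(key == paste(nd$i[b], nd$j[b] + 1)), a2, v2)
    }
  }
  rec(1L, 1L, 2L)
  Ya <- lapply(seq_len(nrow(nd)), function(b)
    vessel_admittance(at$nodes$radius_cm[b], at$nodes$length_cm[b], K_ST,
                      grid, blood, viscosity_mode))
  Yv <- lapply(seq_len(nrow(nd)), function(b)
    vessel_admittance(vt$nodes$radius_cm[b], vt$nodes$length_cm[b], K_ST,
                      grid, blood, viscosity_mode))
  nf <- length(grid$omega)
  out <- matrix(complex(1), nf, 4)
  for (k in seq_len(nf)) {
    G <- matrix(complex(1), nnode, nnode)
    for (e in edges) {
      Y <- if (e$side == "a") Ya[[e$b]] else Yv[[e$b]]
      G[e$n1, e$n1] <- G[e$n1, e$n1] + Y$y11[k]
      G[e$n1, e$n2] <- G[e$n1, e$n2] + Y$y12[k]
      G[e$n2, e$n1] <- G[e$n2, e$n1] + Y$y12[k]
      G[e$n2, e$n2] <- G[e$n2, e$n2] + Y$y11[k]
    }
    P <- 1:2
    I <- 3:nnode
    Yg <- G[P, P] - G[P, I, drop = FALSE] %*% solve(G[I, I], G[I, P, drop = FALSE])
    out[k, ] <- c(Yg[1, 1], Yg[1, 2], Yg[2, 1], Yg[2, 2])
  }
  out
}

grand_as_matrix <- function(Y) cbind(Y$y11, Y$y12, Y$y21, Y$y22)

# Pick-freeze Monte-Carlo Sobol' estimator applied to a function f(theta
# matrix) over uniform bounds; Saltelli/Jansen forms.
pick_freeze_sobol <- function(f, lower, upper, n = 20000, seed = 42) {
  d <- length(lower)
  withr::with_seed(seed, {
    A <- sapply(seq_len(d), function(i) runif(n, lower[i], upper[i]))
    B <- sapply(seq_len(d), function(i) runif(n, lower[i], upper[i]))
  })
  yA <- f(A)
  yB <- f(B)
  varY <- var(c(yA, yB))
  S <- ST <- numeric(d)
  for (i in seq_len(d)) {
    ABi <- A
    ABi[, i] <- B[, i]
    yABi <- f(ABi)
    # Jansen estimators (lower variance than the correlation form)
    S[i] <- 1 - mean((yB - yABi)^2) / (2 * varY)
    ST[i] <- mean((yA - yABi)^2) / (2 * varY)
  }
  list(S = S, ST = ST)
}

# Count local maxima of a periodic trace whose height exceeds a prominence
# floor (fraction of the full range above the minimum).
count_prominent_maxima <- function(x, prominence = 0.02) {
  n <- length(x)
  xm <- c(x[n], x, x[1])
  is_max <- x > xm[1:n] & x >= xm[3:(n + 2)]
  floor_val <- min(x) + prominence * diff(range(x))
  # merge ripple plateaus: keep maxima separated by a real dip
  cand <- which(is_max & x > floor_val)
  if (length(cand) <= 1) return(length(cand))
  keep <- 1
  for (k in seq_along(cand)[-1]) {
    seg <- x[cand[keep[length(keep)]]:cand[k]]
    if (min(seg) < max(x[cand[c(keep[length(keep)], k)]]) - prominence * diff(range(x))) {
      keep <- c(keep, k)
    }
  }
  length(keep)
}
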