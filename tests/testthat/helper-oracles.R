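# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately use explicit loops / quadrature, not the package's
# vectorized code paths.

# exhaustive all-pairs minimum interatomic distance
brute_min_atom_distance <- function(p, q) {
  best <- Inf
  for (i in seq_len(nrow(p$atoms))) for (j in seq_len(nrow(q$atoms))) {
    d <- sqrt((p$atoms$x[i] - q$atoms$x[j])^2 +
              (p$atoms$y[i] - q$atoms$y[j])^2 +
              (p$atoms$z[i] - q$atoms$z[j])^2)
    if (d < best) best <- d
  }
  best
}

# raw Coulomb sum over atom pairs, explicit double loop (cm^-1)
brute_coulomb <- function(p, q) {
  C <- 14.3996 * 8065.544
  acc <- 0
  for (i in seq_len(nrow(p$atoms))) for (j in seq_len(nrow(q$atoms))) {
    d <- sqrt((p$atoms$x[i] - q$atoms$x[j])^2 +
              (p$atoms$y[i] - q$atoms$y[j])^2 +
              (p$atoms$z[i] - q$atoms$z[j])^2)
    acc <- acc + p$atoms$q[i] * q$atoms$q[j] / d
  }
  C * acc
}

# adaptive-quadrature overlap of two Gaussian lineshape densities
quad_overlap <- function(center1, sigma1, center2, sigma2) {
  f <- function(w) dnorm(w, center1, sigma1) * dnorm(w, center2, sigma2)
  lo <- min(center1, center2) - 12 * (sigma1 + sigma2)
  hi <- max(center1, center2) + 12 * (sigma1 + sigma2)
  stats::integrate(f, lo, hi, rel.tol = 1e-12, abs.tol = 0)$value
}

# standalone generalized-Forster rate: explicit loops over exciton states,
# eigen() on a hand-assembled Hamiltonian, quadrature overlaps
brute_generalized_forster <- function(omega_D, V_D, stokes_D, sigma_D,
                                      omega_A, V_A, sigma_A,
                                      site_couplings,
                                      hbar = 5.3088, kB = 0.69504, T = 300) {
  HD <- diag(omega_D, length(omega_D)); HD[upper.tri(HD)] <- V_D
  HD[lower.tri(HD)] <- t(HD)[lower.tri(HD)]
  HA <- diag(omega_A, length(omega_A)); HA[upper.tri(HA)] <- V_A
  HA[lower.tri(HA)] <- t(HA)[lower.tri(HA)]
  eD <- eigen(HD, symmetric = TRUE); eA <- eigen(HA, symmetric = TRUE)
  epsD <- rev(eD$values); CD <- eD$vectors[, rev(seq_along(eD$values))]
  epsA <- rev(eA$values); CA <- eA$vectors[, rev(seq_along(eA$values))]
  w <- exp(-(epsD - min(epsD)) / (kB * T)); w <- w / sum(w)
  k <- 0
  for (a in seq_along(epsD)) for (b in seq_along(epsA)) {
    Vab <- 0
    for (m in seq_along(omega_D)) for (n in seq_along(omega_A))
      Vab <- Vab + CD[m, a] * CA[n, b] * site_couplings[m, n]
    J <- quad_overlap(epsD[a] - stokes_D[a], sigma_D[a], epsA[b], sigma_A[b])
    k <- k + w[a] * (2 * pi / hbar) * Vab^2 * J
  }
  k
}

# enumerate every simple path and its total tau on a small edge list
brute_all_paths <- function(edges, source, sink, max_hops = 6) {
  out <- list()
  walk <- function(node, visited, total) {
    if (node == sink && length(visited) > 1) {
      out[[length(out) + 1L]] <<- list(nodes = visited, total_tau = total)
      return()
    }
    if (length(visited) > max_hops) return()
    nxt <- edges[edges$from == node & !(edges$to %in% visited), ,
                 drop = FALSE]
    for (r in seq_len(nrow(nxt)))
      walk(nxt$to[r], c(visited, nxt$to[r]), total + nxt$tau[r])
  }
  walk(source, source, 0)
  out
}

# charged dimer shortcut
charged_dimer <- function(separation, ...) {
  charge_pigments(make_dimer(separation = separation, ...))
}

# aggregate-ready C2 supercomplex with charges
prepared_supercomplex <- function(...) {
  cx <- make_supercomplex(...)
  gt <- attr(cx, "ground_truth")
  cx2 <- assign_aggregates(cx, gt$aggregate_mapping)
  cx2 <- charge_pigments(cx2)
  attr(cx2, "ground_truth") <- gt
  cx2
}
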