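# Independent brute-force oracle: walk the 2^n reaction network by
# stepwise mass action, building every state concentration from the free
# state along the leftmost-first path. The effective concentrations are
# recomputed here from first principles (Gaussian end-to-end density of
# the combined tether), so the oracle shares no code path with
# configuration_weight()/avidity_exact() above the chain constants.
#
# Works for rigid-geometry models (the kind generate_synthetic_model()
# draws).
oracle_kav <- function(rbp, rna, lp_rna = 2.7, nm_per_nt = 0.55) {
  n <- rbp$n
  ka <- rbp$ka
  dmat <- if (n > 1L) rbp$geometry$distances_nm else matrix(0, 1, 1)
  ceff <- function(i, j) {
    # tether: RNA linkers (+ skipped footprints) between sites i < j
    nt <- sum(rna$linkers_nt[i:(j - 1L)])
    if (j > i + 1L) nt <- nt + sum(rna$footprint_nt[(i + 1L):(j - 1L)])
    s2 <- 2 * lp_rna * (nt * nm_per_nt) / 3
    dens <- (2 * pi * s2)^(-1.5) * exp(-dmat[i, j]^2 / (2 * s2))
    dens * 1e24 / 6.02214076e23           # nm^-3 -> molar
  }
  c_ref <- 1  # reference free-protein concentration (1 M)
  total <- 0
  for (m in seq_len(2^n - 1L)) {
    sites <- which(bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) > 0L)
    # stepwise mass action along the leftmost-first path
    conc <- ka[sites[1L]] * c_ref          # [S1]/[free]
    if (length(sites) > 1L)
      for (k in 2:length(sites))
        conc <- conc * ka[sites[k]] * ceff(sites[k - 1L], sites[k])
    total <- total + conc
  }
  total / c_ref
}

# stationary distribution of a binding_network solved by linear algebra,
# converted to an avidity: an independent cross-check of both the network
# rates and the analytic weights
network_kav_stationary <- function(net, protein_conc) {
  ns <- length(net$configs)
  Q <- matrix(0, ns, ns)
  for (k in seq_along(net$rate)) {
    Q[net$from[k], net$to[k]] <- Q[net$from[k], net$to[k]] + net$rate[k]
  }
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, ns))
  pi_hat <- qr.solve(A, c(rep(0, ns), 1))
  p_bound <- sum(pi_hat[net$bound])
  p_bound / ((1 - p_bound) * protein_conc)
}
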