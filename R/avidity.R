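.N_MAX_ENUM <- 16L   # 2^16 states; exact enumeration is exponential in n

#' Enumerate the 2^n binding configurations
#'
#' A binding configuration is a bitstring of length `n`: character `i` is
#' `"1"` when RNA site `i` is bound by protein domain `i`. For example
#' `"101"` is the configuration with the first and third sites bound. The
#' configurations are returned in stable order of increasing occupation
#' number interpreted site-1-first (`"00" "10" "01" "11"` for n = 2).
#'
#' @param n number of sites, 1 <= n <= 16.
#' @return character vector of length 2^n.
#' @examples
#' enumerate_configurations(2)
#' @export
enumerate_configurations <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1L || n != round(n))
    stop("n must be a positive integer", call. = FALSE)
  if (n > .N_MAX_ENUM)
    stop(sprintf("n = %d exceeds the exact-enumeration capacity (n_max = %d; 2^n states)",
                 n, .N_MAX_ENUM), call. = FALSE)
  n <- as.integer(n)
  vapply(0:(2^n - 1L), function(m)
    paste(ifelse(bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) > 0L, "1", "0"),
          collapse = ""), character(1L))
}

config_sites <- function(config) {
  which(strsplit(config, "")[[1L]] == "1")
}

#' Effective concentration between a pair of sites/domains
#'
#' Local concentration of domain `j` at RNA site `j` when domain `i` is
#' bound to site `i` (or vice versa; the quantity is symmetric). The RNA
#' tether is the chain between the two sites (intervening linkers plus
#' skipped-site footprints); the protein side contributes a fixed 3D offset
#' (rigid geometry) and/or extra Gaussian variance (flexible peptide
#' linkers). RNA and peptide chains fluctuate independently, so per-axis
#' variances add.
#'
#' @param rbp an [rbp_model()].
#' @param rna an [rna_target()] with the same number of sites.
#' @param i,j distinct site indices.
#' @param constants a [chain_constants()] table.
#' @param exact_variance use the Kratky-Porod variance.
#' @param warn warn on chains outside the Gaussian regime.
#' @return an [effective_concentration()].
#' @export
pair_effective_concentration <- function(rbp, rna, i, j,
                                         constants = chain_constants(),
                                         exact_variance = FALSE,
                                         warn = TRUE) {
  n <- check_same_n(rbp, rna)
  if (i == j) stop("i and j must be distinct sites", call. = FALSE)
  lo <- min(i, j); hi <- max(i, j)
  if (lo < 1L || hi > n) stop("site index out of range", call. = FALSE)
  nt <- rna_span_nt(rna, lo, hi)
  rna_chain <- if (nt > 0) rna_linker(nt, constants) else NULL
  geom <- span_geometry(rbp$geometry, lo, hi, constants, exact_variance)
  s2 <- geom$var_nm2
  if (!is.null(rna_chain)) {
    warn_short_chain(list(rna_chain), warn)
    s2 <- s2 + end_to_end_variance(rna_chain, exact = exact_variance)
  }
  model <- if (geom$flexible) "wlc_flexible" else "wlc_rigid"
  effective_concentration(gaussian_c_eff(s2, geom$d_nm), model)
}

#' Statistical weight of one binding configuration
#'
#' The dimensionless weight of a non-empty configuration `S` relative to
#' the free state, `[S] / ([0...0] c)` (with `c` the free protein
#' concentration), carrying the units 1/M of the one bimolecular step. For
#' bound sites `i1 < i2 < ... < im` the weight is
#' \deqn{K_{a,i_1} \prod_{k=2}^{m} c_{i_{k-1} i_k} K_{a,i_k},}
#' i.e. the first bound domain enters bimolecularly and each further domain
#' binds intramolecularly at the local concentration set by the tether to
#' its nearest bound neighbour. Thermodynamics makes the value independent
#' of the order in which the sites are filled.
#'
#' @inheritParams pair_effective_concentration
#' @param config a bitstring such as `"101"`; must contain at least one
#'   `"1"`.
#' @return weight in 1/M.
#' @examples
#' rbp <- rbp_model(kd = c(1e-5, 1e-5), geometry = rigid_geometry(2, n = 2))
#' rna <- rna_target(10)
#' configuration_weight(rbp, rna, "11")
#' @export
configuration_weight <- function(rbp, rna, config,
                                 constants = chain_constants(),
                                 exact_variance = FALSE, warn = TRUE) {
  n <- check_same_n(rbp, rna)
  if (!is.character(config) || length(config) != 1L || nchar(config) != n ||
      grepl("[^01]", config))
    stop("config must be a bitstring of length n", call. = FALSE)
  sites <- config_sites(config)
  if (length(sites) == 0L)
    stop("the empty configuration is the reference state, not a weighted ",
         "bound state", call. = FALSE)
  w <- rbp$ka[sites[1L]]
  if (length(sites) > 1L) {
    for (k in 2:length(sites)) {
      cc <- pair_effective_concentration(rbp, rna, sites[k - 1L], sites[k],
                                         constants, exact_variance,
                                         warn = FALSE)
      w <- w * cc$value * rbp$ka[sites[k]]
    }
  }
  w
}

new_avidity_result <- function(k_av, weights, method) {
  structure(list(k_av = k_av, weights = weights, method = method),
            class = "avidity_result")
}

#' @export
print.avidity_result <- function(x, ...) {
  cat(sprintf("<avidity_result> K_av = %.4g 1/M (Kd = %.4g M), method = %s\n",
              x$k_av, 1 / x$k_av, x$method))
  if (length(x$weights) <= 8L) {
    cat("  configuration weights (1/M):\n")
    for (nm in names(x$weights))
      cat(sprintf("    %s : %.4g\n", nm, x$weights[[nm]]))
  } else {
    cat(sprintf("  %d configuration weights (see $weights)\n",
                length(x$weights)))
  }
  invisible(x)
}

#' Exact avidity by enumeration of all binding configurations
#'
#' The avidity (effective association constant) of an n-domain protein for
#' an n-site RNA is the summed concentration of all bound states divided by
#' the product of the free-species concentrations,
#' \eqn{K_{av} = [\mathrm{all\ bound}] / ([A][B])}. Substituting the
#' stepwise mass-action constants gives the sum of
#' [configuration_weight()] over all \eqn{2^n - 1} non-empty
#' configurations; for n = 2 this is the familiar
#' \eqn{K_{a,1} + K_{a,2} + K_{a,1} c_{12} K_{a,2}}.
#'
#' @inheritParams pair_effective_concentration
#' @return an `avidity_result` with `k_av` (1/M), the per-configuration
#'   `weights`, and `method = "exact"`.
#' @examples
#' rbp <- rbp_model(kd = c(1e-5, 1e-5), geometry = rigid_geometry(2, n = 2))
#' avidity_exact(rbp, rna_target(10))
#' @export
avidity_exact <- function(rbp, rna, constants = chain_constants(),
                          exact_variance = FALSE, warn = TRUE) {
  n <- check_same_n(rbp, rna)
  configs <- enumerate_configurations(n)
  configs <- configs[-1L]   # drop the free state
  w <- vapply(configs, function(cf)
    configuration_weight(rbp, rna, cf, constants, exact_variance,
                         warn = FALSE), numeric(1L))
  if (warn) {
    # consolidated Gaussian-regime warning for the chains actually used
    if (n > 1L && any(vapply(seq_len(n - 1L), function(i) {
      nt <- rna_span_nt(rna, i, i + 1L)
      nt > 0 && is_short_chain(rna_linker(nt, constants))
    }, logical(1L))))
      warning("one or more RNA linkers are outside the Gaussian regime ",
              "(l/(2*l_p) < 5.6); effective concentrations are approximate",
              call. = FALSE)
  }
  new_avidity_result(sum(w), as.list(w), "exact")
}

#' Dominant-path (fully bound) approximation to the avidity
#'
#' When every intramolecular step is strongly favourable
#' (\eqn{K_{a,i} c_{i-1,i} \gg 1}), the fully bound configuration dominates
#' the sum over states and
#' \deqn{K_{av} \approx K_{a,1}\, c_{12} K_{a,2}\, c_{23} \cdots
#'       c_{n-1,n} K_{a,n}.}
#' A validity warning is emitted when any step factor
#' \eqn{K_{a,i} c_{i-1,i}} is below 10.
#'
#' @inheritParams avidity_exact
#' @return an `avidity_result` with `method = "approx"` and the single
#'   fully-bound-path weight.
#' @export
avidity_approx <- function(rbp, rna, constants = chain_constants(),
                           exact_variance = FALSE, warn = TRUE) {
  n <- check_same_n(rbp, rna)
  w <- rbp$ka[1L]
  min_step <- Inf
  if (n > 1L) {
    for (i in 2:n) {
      cc <- pair_effective_concentration(rbp, rna, i - 1L, i, constants,
                                         exact_variance, warn = FALSE)
      step <- cc$value * rbp$ka[i]
      min_step <- min(min_step, step)
      w <- w * step
    }
    if (warn && min_step < 10)
      warning(sprintf(paste0("dominant-path approximation of limited ",
                             "validity: smallest step factor Ka*c = %.3g ",
                             "(< 10)"), min_step), call. = FALSE)
  }
  full <- paste(rep("1", n), collapse = "")
  new_avidity_result(w, setNames(list(w), full), "approx")
}

#' Two-site avidity with same-specificity ("fuzzy") domains
#'
#' When both domains recognise the same motif, each domain can bind either
#' of the two RNA sites, adding the swapped domain-site assignments to the
#' reaction network. With one protein per RNA the bound states are the four
#' singly-bound assignments plus the two doubly-bound pairings (parallel:
#' domain 1 on site 1 and domain 2 on site 2; crossed: domain 1 on site 2
#' and domain 2 on site 1), giving
#' \deqn{K_{av} = \sum_{d,s} K_a[d,s] + K_a[1,1]\,c_{par}\,K_a[2,2]
#'       + K_a[1,2]\,c_{cross}\,K_a[2,1].}
#' With zero off-diagonal affinities this reduces exactly to the strictly
#' matched two-site avidity.
#'
#' @param ka 2 x 2 matrix of association constants (1/M), `ka[d, s]` for
#'   domain `d` on site `s`. Entries may be 0 (no binding).
#' @param c_parallel,c_crossed effective concentrations (M, or
#'   [effective_concentration()]) for the parallel and crossed doubly-bound
#'   pairings.
#' @return an `avidity_result` with `method = "fuzzy"`.
#' @export
avidity_fuzzy_two_site <- function(ka, c_parallel, c_crossed = c_parallel) {
  if (!is.matrix(ka) || !all(dim(ka) == c(2L, 2L)))
    stop("fuzzy binding is implemented for n = 2 only: ka must be 2 x 2",
         call. = FALSE)
  if (any(!is.finite(ka)) || any(ka < 0))
    stop("ka entries must be finite and >= 0", call. = FALSE)
  cp <- conc_value(c_parallel); cx <- conc_value(c_crossed)
  if (cp <= 0 || cx <= 0)
    stop("effective concentrations must be positive", call. = FALSE)
  singles <- sum(ka)
  w_par <- ka[1L, 1L] * cp * ka[2L, 2L]
  w_cross <- ka[1L, 2L] * cx * ka[2L, 1L]
  weights <- list(`10` = ka[1L, 1L] + ka[2L, 1L],
                  `01` = ka[1L, 2L] + ka[2L, 2L],
                  `11_parallel` = w_par, `11_crossed` = w_cross)
  new_avidity_result(singles + w_par + w_cross,
                     weights[vapply(weights, function(x) x > 0, logical(1L))],
                     "fuzzy")
}

#' Register-multiplicity adjustment of a single-domain affinity
#'
#' A domain binding within a repetitive motif (e.g. a mono- or dinucleotide
#' repeat) can bind in any of `n_registers` overlapping positions; by
#' simple state counting this multiplies the association constant by
#' `n_registers` (equivalently divides the Kd by that factor).
#'
#' @param ka association constant in 1/M.
#' @param n_registers number of binding registers, integer >= 1.
#' @return adjusted association constant in 1/M.
#' @examples
#' register_adjusted_ka(2e4, 3)  # 6e4
#' @export
register_adjusted_ka <- function(ka, n_registers) {
  if (!is.numeric(ka) || any(ka <= 0))
    stop("ka must be positive", call. = FALSE)
  if (!is.numeric(n_registers) || length(n_registers) != 1L ||
      n_registers < 1 || n_registers != round(n_registers))
    stop("n_registers must be an integer >= 1", call. = FALSE)
  ka * n_registers
}

#' Equilibrium occupancy at a given ligand concentration
#'
#' Binding probability of the multivalent pair at ligand concentration
#' `ligand_conc`, \eqn{[L] / (K_{av}^{-1} + [L])}.
#'
#' @param k_av avidity in 1/M (or an `avidity_result`).
#' @param ligand_conc ligand concentration in M.
#' @return probability in (0, 1).
#' @examples
#' occupancy(1e7, 1e-7)  # 0.5 at the midpoint
#' @export
occupancy <- function(k_av, ligand_conc) {
  if (inherits(k_av, "avidity_result")) k_av <- k_av$k_av
  if (any(!is.finite(k_av)) || any(k_av <= 0))
    stop("k_av must be positive", call. = FALSE)
  if (any(!is.finite(ligand_conc)) || any(ligand_conc <= 0))
    stop("ligand_conc must be positive", call. = FALSE)
  ligand_conc / (1 / k_av + ligand_conc)
}
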