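#' Semi-flexible polymer segment
#'
#' A `chain_segment` describes one worm-like chain: an ssRNA linker between
#' two binding motifs or a disordered peptide linker between two protein
#' domains. It carries the contour length `l` (nm) and the persistence
#' length `l_p` (nm).
#'
#' @param contour_length_nm contour length in nm, > 0.
#' @param persistence_length_nm persistence length in nm, > 0.
#' @param kind `"rna"` or `"peptide"`; informational.
#' @return object of class `chain_segment`.
#' @seealso [rna_linker()], [peptide_linker()] for sequence-length based
#'   constructors.
#' @examples
#' chain_segment(5.5, 2.7, "rna")
#' @export
chain_segment <- function(contour_length_nm, persistence_length_nm,
                          kind = c("rna", "peptide")) {
  kind <- match.arg(kind)
  if (!is.numeric(contour_length_nm) || length(contour_length_nm) != 1L ||
      !is.finite(contour_length_nm) || contour_length_nm <= 0)
    stop("contour_length_nm must be a single positive number", call. = FALSE)
  if (!is.numeric(persistence_length_nm) || length(persistence_length_nm) != 1L ||
      !is.finite(persistence_length_nm) || persistence_length_nm <= 0)
    stop("persistence_length_nm must be a single positive number", call. = FALSE)
  structure(list(contour_length_nm = contour_length_nm,
                 persistence_length_nm = persistence_length_nm,
                 kind = kind),
            class = "chain_segment")
}

#' @export
print.chain_segment <- function(x, ...) {
  cat(sprintf("<chain_segment> %s: l = %.3g nm, l_p = %.3g nm\n",
              x$kind, x$contour_length_nm, x$persistence_length_nm))
  invisible(x)
}

#' Contour length of an RNA or peptide chain
#'
#' Multiplies the number of monomers by the per-monomer contour length
#' (0.55 nm per nucleotide, 0.38 nm per amino acid by default).
#'
#' @param count number of nucleotides or amino acids, >= 1.
#' @param kind `"rna"` or `"peptide"`.
#' @param constants a [chain_constants()] table.
#' @return contour length in nm.
#' @examples
#' contour_length(10, "rna")      # 5.5 nm
#' contour_length(10, "peptide")  # 3.8 nm
#' @export
contour_length <- function(count, kind = c("rna", "peptide"),
                           constants = chain_constants()) {
  kind <- match.arg(kind)
  if (!is.numeric(count) || any(!is.finite(count)) || any(count <= 0))
    stop("count must be positive", call. = FALSE)
  per <- if (kind == "rna") constants$nm_per_nt else constants$nm_per_aa
  count * per
}

#' @rdname chain_segment
#' @param nt,aa number of nucleotides / amino acids (> 0).
#' @param constants a [chain_constants()] table supplying per-monomer lengths
#'   and default persistence lengths.
#' @export
rna_linker <- function(nt, constants = chain_constants()) {
  chain_segment(contour_length(nt, "rna", constants),
                constants$lp_rna_nm, "rna")
}

#' @rdname chain_segment
#' @export
peptide_linker <- function(aa, constants = chain_constants()) {
  chain_segment(contour_length(aa, "peptide", constants),
                constants$lp_peptide_nm, "peptide")
}

#' Effective local concentration container
#' @param value concentration in molar, > 0.
#' @param model one of `"sphere"`, `"wlc_rigid"`, `"wlc_flexible"`.
#' @return object of class `effective_concentration`; behaves as a number
#'   via `as.numeric()`.
#' @export
effective_concentration <- function(value,
                                    model = c("sphere", "wlc_rigid",
                                              "wlc_flexible")) {
  model <- match.arg(model)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value <= 0)
    stop("effective concentration must be a single positive number",
         call. = FALSE)
  structure(list(value = value, model = model),
            class = "effective_concentration")
}

#' @export
print.effective_concentration <- function(x, ...) {
  cat(sprintf("<effective_concentration> %.4g M (%s)\n", x$value, x$model))
  invisible(x)
}

#' @export
as.numeric.effective_concentration <- function(x, ...) x$value

# accept either a bare number (molar) or an effective_concentration
conc_value <- function(x) {
  if (inherits(x, "effective_concentration")) x$value else as.numeric(x)
}

#' Particle-in-a-sphere effective concentration
#'
#' The crudest estimate of the local concentration of a tethered partner:
#' one molecule distributed uniformly in a sphere whose radius is the chain
#' length `l` between the two attachment points,
#' \eqn{c = (N_A \cdot \frac{4}{3}\pi l^3)^{-1}}.
#'
#' @param l_nm chain length (sphere radius) in nm, > 0.
#' @return an [effective_concentration()] with `model = "sphere"`.
#' @examples
#' c_sphere(1)  # ~0.40 M
#' @export
c_sphere <- function(l_nm) {
  if (!is.numeric(l_nm) || length(l_nm) != 1L || !is.finite(l_nm) || l_nm <= 0)
    stop("l_nm must be a single positive length", call. = FALSE)
  dens_nm3 <- 1 / (4 / 3 * pi * l_nm^3)   # molecules per nm^3
  effective_concentration(nm3_to_molar(dens_nm3), "sphere")
}

#' Per-axis variance of the worm-like-chain end-to-end vector
#'
#' In the long-chain (Gaussian) limit the mean squared end-to-end distance
#' of a worm-like chain is \eqn{\langle r^2\rangle = 2\,l_p\,l}; the
#' end-to-end vector is isotropic Gaussian with per-axis variance
#' \eqn{\sigma^2 = \langle r^2\rangle/3}. With `exact = TRUE` the full
#' Kratky-Porod expression
#' \eqn{\langle r^2\rangle = 2 l_p l - 2 l_p^2 (1 - e^{-l/l_p})}
#' is used instead; it matters only for chains shorter than a few
#' persistence lengths, where the Gaussian shape assumption itself breaks
#' down (see Details).
#'
#' @details For stiff chains (\eqn{l/(2 l_p) < 5.6}) the true end-to-end
#'   distribution is not an isotropic Gaussian and has no single maximum at
#'   the origin; the Gaussian limit then over- or under-estimates the local
#'   concentration depending on the attachment geometry. Functions that
#'   consume this variance emit a one-time warning in that regime but still
#'   compute.
#'
#' @param chain a [chain_segment()].
#' @param exact use the Kratky-Porod finite-chain correction.
#' @return per-axis variance in nm^2.
#' @examples
#' end_to_end_variance(chain_segment(5.5, 2.7, "rna"))  # 9.9 nm^2
#' @export
end_to_end_variance <- function(chain, exact = FALSE) {
  stopifnot(inherits(chain, "chain_segment"))
  l <- chain$contour_length_nm
  lp <- chain$persistence_length_nm
  r2 <- if (exact) 2 * lp * l - 2 * lp^2 * (1 - exp(-l / lp)) else 2 * lp * l
  r2 / 3
}

# Gaussian-regime check; the threshold is where the radial end-to-end
# density first acquires a single maximum near the origin.
is_short_chain <- function(chain) {
  chain$contour_length_nm / (2 * chain$persistence_length_nm) < 5.6
}

warn_short_chain <- function(chains, warn) {
  if (warn && any(vapply(chains, is_short_chain, logical(1L))))
    warning("chain shorter than the Gaussian regime (l/(2*l_p) < 5.6); ",
            "the isotropic-Gaussian effective concentration is an ",
            "approximation here", call. = FALSE)
}

# isotropic Gaussian number density (nm^-3) at radius d, converted to molar
gaussian_c_eff <- function(sigma2_nm2, d_nm) {
  if (sigma2_nm2 <= 0)
    stop("total chain variance must be positive (zero-length tether?)",
         call. = FALSE)
  dens <- (2 * pi * sigma2_nm2)^(-1.5) * exp(-d_nm^2 / (2 * sigma2_nm2))
  nm3_to_molar(dens)
}

#' Worm-like-chain effective concentration, rigidly linked domains
#'
#' Local concentration of a tethered binding partner when the two protein
#' domains are rigidly linked at 3D distance `d` and the tether is a single
#' RNA worm-like chain: the isotropic Gaussian end-to-end density of the
#' chain, evaluated at radial distance `d` and converted to molar.
#'
#' @param rna_chain a [chain_segment()] describing the RNA linker.
#' @param d_nm 3D distance between the domain attachment points, >= 0.
#' @param exact_variance use the Kratky-Porod variance
#'   (see [end_to_end_variance()]).
#' @param warn warn when the chain is outside the Gaussian regime.
#' @return an [effective_concentration()] with `model = "wlc_rigid"`.
#' @examples
#' c_eff_rigid(rna_linker(10), d_nm = 2)   # ~2.8 mM
#' @export
c_eff_rigid <- function(rna_chain, d_nm, exact_variance = FALSE, warn = TRUE) {
  stopifnot(inherits(rna_chain, "chain_segment"))
  if (!is.numeric(d_nm) || length(d_nm) != 1L || !is.finite(d_nm) || d_nm < 0)
    stop("d_nm must be a single non-negative distance", call. = FALSE)
  warn_short_chain(list(rna_chain), warn)
  s2 <- end_to_end_variance(rna_chain, exact = exact_variance)
  effective_concentration(gaussian_c_eff(s2, d_nm), "wlc_rigid")
}

#' Worm-like-chain effective concentration, flexibly linked domains
#'
#' When the protein domains are themselves connected by flexible peptide
#' linkers, the RNA linker and each peptide linker fluctuate independently;
#' the end-to-end vector of the combined tether is the convolution of the
#' individual Gaussians, i.e. a Gaussian whose per-axis variance is the sum
#' of the per-axis variances. `d_residual_nm` is any remaining fixed offset
#' (rigid parts of the geometry), at which the combined density is
#' evaluated.
#'
#' @param rna_chain a [chain_segment()] for the RNA linker.
#' @param peptide_chains list of [chain_segment()]s for the peptide linkers
#'   spanning the two domains (may be empty, in which case the result equals
#'   [c_eff_rigid()]).
#' @param d_residual_nm residual fixed 3D offset in nm, >= 0.
#' @inheritParams c_eff_rigid
#' @return an [effective_concentration()] with `model = "wlc_flexible"`
#'   (or `"wlc_rigid"` when `peptide_chains` is empty).
#' @examples
#' c_eff_flexible(rna_linker(20), list(peptide_linker(15)), 0)
#' @export
c_eff_flexible <- function(rna_chain, peptide_chains = list(),
                           d_residual_nm = 0, exact_variance = FALSE,
                           warn = TRUE) {
  stopifnot(inherits(rna_chain, "chain_segment"))
  if (!is.list(peptide_chains) ||
      !all(vapply(peptide_chains, inherits, logical(1L), "chain_segment")))
    stop("peptide_chains must be a (possibly empty) list of chain_segment",
         call. = FALSE)
  if (!is.numeric(d_residual_nm) || length(d_residual_nm) != 1L ||
      !is.finite(d_residual_nm) || d_residual_nm < 0)
    stop("d_residual_nm must be a single non-negative distance",
         call. = FALSE)
  all_chains <- c(list(rna_chain), peptide_chains)
  warn_short_chain(all_chains, warn)
  s2 <- sum(vapply(all_chains, end_to_end_variance, numeric(1L),
                   exact = exact_variance))
  model <- if (length(peptide_chains) == 0L) "wlc_rigid" else "wlc_flexible"
  effective_concentration(gaussian_c_eff(s2, d_residual_nm), model)
}
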