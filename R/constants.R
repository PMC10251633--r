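#' Avogadro's number (mol^-1)
#' @keywords internal
.AVOGADRO <- 6.02214076e23

#' Conversion factor: number density of 1 molecule per nm^3 in molar
#'
#' 1 nm^-3 = 1e24 L^-1 = 1e24 / N_A mol/L = 1.66054 M.
#' @keywords internal
.NM3_TO_MOLAR <- 1e24 / .AVOGADRO

#' Convert a number density in nm^-3 to a molar concentration
#'
#' One molecule per cubic nanometre corresponds to
#' \eqn{10^{24}/N_A \approx 1.66054} mol/L. This single conversion factor is
#' used everywhere in the package so that polymer statistics (in nm) and
#' binding thermodynamics (in molar) share one unit boundary.
#'
#' @param x number density in nm^-3 (for `nm3_to_molar`) or concentration in
#'   molar (for `molar_to_nm3`).
#' @return numeric of the same length as `x`.
#' @examples
#' nm3_to_molar(1)            # ~1.66 M
#' molar_to_nm3(nm3_to_molar(0.5))  # 0.5, to machine precision
#' @export
nm3_to_molar <- function(x) x * .NM3_TO_MOLAR

#' @rdname nm3_to_molar
#' @export
molar_to_nm3 <- function(x) x / .NM3_TO_MOLAR

#' Chain parameter table
#'
#' Default polymer parameters used to convert sequence lengths into
#' worm-like-chain (WLC) parameters:
#' \describe{
#'   \item{nm_per_nt}{contour length per RNA nucleotide, 0.55 nm (5.5 A).}
#'   \item{nm_per_aa}{contour length per amino acid of a disordered peptide,
#'     0.38 nm (3.8 A).}
#'   \item{lp_rna_nm}{persistence length of single-stranded RNA, 2.7 nm.}
#'   \item{lp_peptide_nm}{persistence length of a disordered peptide,
#'     0.304 nm (3.04 A).}
#' }
#' All values can be overridden per call; every higher-level operation
#' accepts a `constants` argument so that one table flows through a whole
#' computation.
#'
#' @param nm_per_nt,nm_per_aa,lp_rna_nm,lp_peptide_nm override any default.
#' @return a named list of class `chain_constants`.
#' @examples
#' chain_constants()
#' chain_constants(lp_rna_nm = 1.9)  # stiffer-sequence override
#' @export
chain_constants <- function(nm_per_nt = 0.55, nm_per_aa = 0.38,
                            lp_rna_nm = 2.7, lp_peptide_nm = 0.304) {
  stopifnot(nm_per_nt > 0, nm_per_aa > 0, lp_rna_nm > 0, lp_peptide_nm > 0)
  structure(list(nm_per_nt = nm_per_nt, nm_per_aa = nm_per_aa,
                 lp_rna_nm = lp_rna_nm, lp_peptide_nm = lp_peptide_nm),
            class = "chain_constants")
}

#' @export
print.chain_constants <- function(x, ...) {
  cat("Chain constants:\n")
  cat(sprintf("  contour per nt : %.4g nm\n", x$nm_per_nt))
  cat(sprintf("  contour per aa : %.4g nm\n", x$nm_per_aa))
  cat(sprintf("  l_p ssRNA      : %.4g nm\n", x$lp_rna_nm))
  cat(sprintf("  l_p peptide    : %.4g nm\n", x$lp_peptide_nm))
  invisible(x)
}

#' Format the constants table as `key=value` pairs (used in CLI log headers)
#' @keywords internal
format_constants <- function(constants) {
  paste(sprintf("%s=%g", names(constants), unlist(constants)), collapse = " ")
}
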