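#' Inter-domain geometry of a multi-domain protein
#'
#' Three geometry flavours describe how the RNA-binding domains of one
#' protein are connected:
#' \describe{
#'   \item{`rigid_geometry(distances_nm)`}{domains move as one rigid body;
#'     `distances_nm` is the symmetric n x n matrix of 3D distances between
#'     domain attachment points (zero diagonal, entries >= 0). A scalar or a
#'     length n-1 vector of consecutive distances is expanded to the
#'     collinear matrix `d_ij = sum of the gap distances between i and j`.}
#'   \item{`flexible_geometry(linkers_aa, residual_nm = 0)`}{consecutive
#'     domains are joined by disordered peptide linkers of the given lengths
#'     (amino acids, one per gap); `residual_nm` is an optional fixed offset
#'     per gap (default 0).}
#'   \item{`mixed_geometry(gaps)`}{per-gap list mixing the two: each element
#'     is either `list(type = "rigid", d_nm = ...)` or
#'     `list(type = "flexible", aa = ..., residual_nm = 0)`. Rigid offsets of
#'     spanned gaps add collinearly.}
#' }
#'
#' @param distances_nm symmetric distance matrix (nm), or a scalar /
#'   per-gap vector of consecutive distances expanded collinearly.
#' @param n number of domains (required when `distances_nm` is a scalar).
#' @return an object of class `rbp_geometry`.
#' @name rbp_geometry
NULL

#' @rdname rbp_geometry
#' @export
rigid_geometry <- function(distances_nm, n = NULL) {
  if (is.matrix(distances_nm)) {
    d <- distances_nm
  } else {
    gaps <- as.numeric(distances_nm)
    if (length(gaps) == 1L) {
      if (is.null(n))
        stop("n is required to expand a scalar distance", call. = FALSE)
      gaps <- rep(gaps, max(n - 1L, 0L))
    }
    n <- length(gaps) + 1L
    d <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      if (i != j) d[i, j] <- sum(gaps[min(i, j):(max(i, j) - 1L)])
  }
  if (nrow(d) != ncol(d) || any(d < 0) || any(diag(d) != 0) ||
      !isTRUE(all.equal(d, t(d))))
    stop("rigid geometry needs a symmetric, non-negative distance matrix ",
         "with zero diagonal", call. = FALSE)
  structure(list(type = "rigid", distances_nm = d, n = nrow(d)),
            class = "rbp_geometry")
}

#' @rdname rbp_geometry
#' @param linkers_aa peptide linker lengths in amino acids, one per gap.
#' @param residual_nm fixed residual 3D offset per gap (nm), recycled.
#' @export
flexible_geometry <- function(linkers_aa, residual_nm = 0) {
  linkers_aa <- as.numeric(linkers_aa)
  if (length(linkers_aa) < 1L || any(!is.finite(linkers_aa)) ||
      any(linkers_aa <= 0))
    stop("linkers_aa must be positive peptide lengths, one per gap",
         call. = FALSE)
  residual_nm <- rep_len(as.numeric(residual_nm), length(linkers_aa))
  if (any(residual_nm < 0))
    stop("residual_nm must be non-negative", call. = FALSE)
  structure(list(type = "flexible", linkers_aa = linkers_aa,
                 residual_nm = residual_nm, n = length(linkers_aa) + 1L),
            class = "rbp_geometry")
}

#' @rdname rbp_geometry
#' @param gaps per-gap list for `mixed_geometry` (see Description).
#' @export
mixed_geometry <- function(gaps) {
  if (!is.list(gaps) || length(gaps) < 1L)
    stop("gaps must be a non-empty list", call. = FALSE)
  for (g in gaps) {
    if (is.null(g$type) || !g$type %in% c("rigid", "flexible"))
      stop("each gap needs type 'rigid' or 'flexible'", call. = FALSE)
    if (g$type == "rigid" &&
        (is.null(g$d_nm) || !is.finite(g$d_nm) || g$d_nm < 0))
      stop("rigid gap needs a non-negative d_nm", call. = FALSE)
    if (g$type == "flexible" &&
        (is.null(g$aa) || !is.finite(g$aa) || g$aa <= 0))
      stop("flexible gap needs a positive aa length", call. = FALSE)
  }
  structure(list(type = "mixed", gaps = gaps, n = length(gaps) + 1L),
            class = "rbp_geometry")
}

#' @export
print.rbp_geometry <- function(x, ...) {
  cat(sprintf("<rbp_geometry> %s, %d domain(s)\n", x$type, x$n))
  invisible(x)
}

# Protein-side geometry spanned between domains i < j: a fixed 3D offset
# (nm) plus extra per-axis Gaussian variance (nm^2) from flexible linkers.
span_geometry <- function(geometry, i, j, constants = chain_constants(),
                          exact_variance = FALSE) {
  stopifnot(inherits(geometry, "rbp_geometry"), i < j)
  if (geometry$type == "rigid")
    return(list(d_nm = geometry$distances_nm[i, j], var_nm2 = 0,
                flexible = FALSE))
  gap_idx <- i:(j - 1L)
  if (geometry$type == "flexible") {
    v <- sum(vapply(geometry$linkers_aa[gap_idx], function(aa)
      end_to_end_variance(peptide_linker(aa, constants),
                          exact = exact_variance), numeric(1L)))
    return(list(d_nm = sum(geometry$residual_nm[gap_idx]), var_nm2 = v,
                flexible = TRUE))
  }
  # mixed: rigid offsets add collinearly, flexible gaps add variance
  d <- 0; v <- 0
  for (g in geometry$gaps[gap_idx]) {
    if (g$type == "rigid") {
      d <- d + g$d_nm
    } else {
      v <- v + end_to_end_variance(peptide_linker(g$aa, constants),
                                   exact = exact_variance)
      d <- d + (if (is.null(g$residual_nm)) 0 else g$residual_nm)
    }
  }
  list(d_nm = d, var_nm2 = v, flexible = v > 0)
}

#' Multi-domain RNA-binding protein model
#'
#' An ordered set of RNA-binding domains, each with a single-domain
#' association constant, plus the inter-domain geometry. Domain `i` binds
#' RNA site `i` (strictly matched binding; see [avidity_fuzzy_two_site()]
#' for the same-specificity two-site case).
#'
#' @param kd per-domain dissociation constants in molar (alternative to
#'   `ka`).
#' @param ka per-domain association constants in 1/molar.
#' @param geometry an [rbp_geometry] (may be `NULL` for n = 1).
#' @return object of class `rbp_model` with fields `ka` (1/M), `n`,
#'   `geometry`.
#' @examples
#' rbp_model(kd = c(50e-6, 50e-6), geometry = rigid_geometry(2, n = 2))
#' @export
rbp_model <- function(kd = NULL, ka = NULL, geometry = NULL) {
  if (is.null(ka) == is.null(kd))
    stop("supply exactly one of ka (1/M) or kd (M)", call. = FALSE)
  if (is.null(ka)) {
    if (any(!is.finite(kd)) || any(kd <= 0))
      stop("all kd must be positive and finite (in molar)", call. = FALSE)
    ka <- 1 / as.numeric(kd)
  }
  ka <- as.numeric(ka)
  if (length(ka) < 1L || any(!is.finite(ka)) || any(ka <= 0))
    stop("all ka must be positive and finite (in 1/molar)", call. = FALSE)
  n <- length(ka)
  if (n > 1L) {
    if (is.null(geometry))
      stop("geometry is required for more than one domain", call. = FALSE)
    stopifnot(inherits(geometry, "rbp_geometry"))
    if (geometry$n != n)
      stop(sprintf("geometry describes %d domains but %d affinities given",
                   geometry$n, n), call. = FALSE)
  }
  structure(list(ka = ka, n = n, geometry = geometry), class = "rbp_model")
}

#' @export
print.rbp_model <- function(x, ...) {
  cat(sprintf("<rbp_model> %d domain(s); Kd = %s uM; geometry: %s\n", x$n,
              paste(signif(1e6 / x$ka, 3), collapse = ", "),
              if (is.null(x$geometry)) "none" else x$geometry$type))
  invisible(x)
}

#' RNA target with ordered binding sites
#'
#' `n` binding sites in fixed order, separated by `n - 1` single-stranded
#' linkers. `motif_footprint_nt` is the footprint of each site; when a
#' configuration skips a site, the RNA tether between the flanking bound
#' sites is the sum of the intervening linkers plus the footprints of the
#' skipped sites.
#'
#' @param linkers_nt linker lengths between consecutive sites in
#'   nucleotides (>= 0); `numeric(0)` gives a single-site RNA.
#' @param motif_footprint_nt per-site footprint in nt (scalar recycled),
#'   default 0.
#' @return object of class `rna_target` with fields `n`, `linkers_nt`,
#'   `footprint_nt`.
#' @examples
#' rna_target(c(10, 10))          # three sites, two 10-nt linkers
#' rna_target(numeric(0))         # single site
#' @export
rna_target <- function(linkers_nt, motif_footprint_nt = 0) {
  linkers_nt <- as.numeric(linkers_nt)
  if (any(!is.finite(linkers_nt)) || any(linkers_nt < 0))
    stop("linker lengths must be non-negative (nt)", call. = FALSE)
  n <- length(linkers_nt) + 1L
  fp <- rep_len(as.numeric(motif_footprint_nt), n)
  if (any(!is.finite(fp)) || any(fp < 0))
    stop("motif footprints must be non-negative (nt)", call. = FALSE)
  structure(list(n = n, linkers_nt = linkers_nt, footprint_nt = fp),
            class = "rna_target")
}

#' @export
print.rna_target <- function(x, ...) {
  cat(sprintf("<rna_target> %d site(s); linkers = %s nt\n", x$n,
              if (x$n == 1L) "-" else paste(x$linkers_nt, collapse = ", ")))
  invisible(x)
}

# RNA tether length in nt between bound sites i < j: intervening linkers
# plus footprints of the skipped sites.
rna_span_nt <- function(rna, i, j) {
  stopifnot(inherits(rna, "rna_target"), i < j, j <= rna$n)
  span <- sum(rna$linkers_nt[i:(j - 1L)])
  if (j > i + 1L) span <- span + sum(rna$footprint_nt[(i + 1L):(j - 1L)])
  span
}

check_same_n <- function(rbp, rna) {
  stopifnot(inherits(rbp, "rbp_model"), inherits(rna, "rna_target"))
  if (rbp$n != rna$n)
    stop(sprintf("protein has %d domains but RNA has %d sites",
                 rbp$n, rna$n), call. = FALSE)
  invisible(rbp$n)
}
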