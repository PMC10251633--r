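#' Avidity of an n-domain protein on an RNA with N >= n sites
#'
#' On a long RNA with `N` equally spaced sites, a protein whose `n` domains
#' bind adjacent sites can be placed in `N - n + 1` registers; when the
#' fully bound configurations dominate, the avidity is approximately the
#' n-site avidity times that multiplicity,
#' \eqn{K_{av}(N, n) \approx K_{av} (N - n + 1)}.
#'
#' @param base n-site avidity: an `avidity_result` or a number in 1/M.
#' @param N number of binding sites on the RNA, `N >= n`.
#' @param n number of protein domains.
#' @return avidity in 1/M.
#' @examples
#' avidity_at_density(1e7, N = 10, n = 4)  # 7e7
#' @export
avidity_at_density <- function(base, N, n) {
  if (inherits(base, "avidity_result")) base <- base$k_av
  if (any(N < n)) stop("N must be >= n", call. = FALSE)
  base * (N - n + 1)
}

# collinear rigid protein used in density scans: consecutive domains at
# distance d_nm, so d_ij = |i - j| * d_nm
scan_rbp <- function(n, ka, d_nm) {
  geom <- if (n > 1L) rigid_geometry(d_nm, n = n) else NULL
  rbp_model(ka = rep(ka, n), geometry = geom)
}

#' Avidity and occupancy as a function of binding-site density
#'
#' Scans the number of binding sites `N` on an RNA of fixed length `L`
#' (density `D = N/L` in sites per nt). For each `N`, the `n` protein
#' domains see `n` adjacent sites separated by equal linkers of `L/N` nt
#' (or `L/(N-1)` under the alternative spacing convention); the exact
#' n-site avidity is computed with rigidly linked domains at consecutive
#' distance `d_nm` (collinear, `d_ij = |i-j| d`), multiplied by the
#' placement multiplicity `N - n + 1` ([avidity_at_density()]), and
#' converted to an occupancy at RNA concentration `rna_conc`.
#'
#' The default grid is 200 site counts log-spaced in density from one site
#' on the whole RNA (`1/L`) up to `density_max` = 0.2 sites/nt; binding
#' motifs are several nucleotides long, so substantially higher densities
#' are not physically meaningful. Site counts below `n` are skipped (with a
#' warning if they were requested explicitly).
#'
#' @param n_domains number of protein domains (= sites bound), >= 1.
#' @param kd per-domain dissociation constant in M (scalar; all domains
#'   equal).
#' @param rna_length_nt total RNA length L in nt.
#' @param rna_conc RNA concentration in M used for the occupancy column.
#' @param d_nm 3D distance between consecutive rigidly linked domains (nm).
#' @param site_counts optional explicit vector of site counts N (may be
#'   non-integer for a smooth curve); defaults to the log-spaced grid.
#' @param density_max upper end of the default density grid (sites/nt).
#' @param grid_points number of points of the default grid.
#' @param spacing `"L/N"` (linkers of L/N nt; density and linker length are
#'   exactly reciprocal) or `"L/(N-1)"` (sites span the full RNA).
#' @param motif_footprint_nt per-site footprint subtracted from nothing but
#'   recorded on the [rna_target()]s used (default 0).
#' @param constants a [chain_constants()] table.
#' @return `data.frame` with columns `N`, `density_per_nt`, `kav_per_M`,
#'   `inv_kav_M`, `occupancy`.
#' @examples
#' scan <- density_scan(2, kd = 50e-6, rna_length_nt = 200,
#'                      rna_conc = 1e-7, d_nm = 2, grid_points = 40)
#' head(scan)
#' @export
density_scan <- function(n_domains, kd, rna_length_nt, rna_conc,
                         d_nm = 2, site_counts = NULL, density_max = 0.2,
                         grid_points = 200L,
                         spacing = c("L/N", "L/(N-1)"),
                         motif_footprint_nt = 0,
                         constants = chain_constants()) {
  spacing <- match.arg(spacing)
  n <- as.integer(n_domains)
  stopifnot(n >= 1L, kd > 0, rna_length_nt > 0, rna_conc > 0, d_nm >= 0)
  L <- rna_length_nt
  if (is.null(site_counts)) {
    dens <- exp(seq(log(1 / L), log(density_max), length.out = grid_points))
    site_counts <- dens * L
    site_counts <- site_counts[site_counts >= n]
  } else {
    drop <- site_counts < n
    if (any(drop)) {
      warning(sprintf("skipping %d site count(s) below n_domains = %d",
                      sum(drop), n), call. = FALSE)
      site_counts <- site_counts[!drop]
    }
  }
  if (length(site_counts) == 0L)
    stop("no usable site counts (all below n_domains)", call. = FALSE)
  site_counts <- sort(site_counts)
  ka <- 1 / kd
  rbp <- scan_rbp(n, ka, d_nm)
  kav <- vapply(site_counts, function(N) {
    linker <- if (spacing == "L/N") L / N else L / (N - 1)
    rna <- rna_target(rep(linker, n - 1L), motif_footprint_nt)
    base <- avidity_exact(rbp, rna, constants, warn = FALSE)
    avidity_at_density(base, N, n)
  }, numeric(1L))
  data.frame(N = site_counts,
             density_per_nt = site_counts / L,
             kav_per_M = kav,
             inv_kav_M = 1 / kav,
             occupancy = occupancy(kav, rna_conc))
}

#' Fit a Hill function to occupancy versus binding-site density
#'
#' Least-squares fit of the two-parameter sigmoidal Hill function
#' \eqn{f(D) = 1 / (1 + (D_0 / D)^h)} to binding probability as a function
#' of binding-site density `D`. The Hill coefficient `h` measures the
#' cooperativity (switch-likeness) of the density response; `D0` is the
#' midpoint density.
#'
#' The fit is performed on linear occupancy with the Levenberg-Marquardt
#' algorithm, starting from `h = n_domains` and `D0` at the scanned density
#' nearest half-occupancy, with `h` bounded in `(0, 5 n_domains]`.
#'
#' @param densities binding-site densities (sites/nt), >= 4 values.
#' @param occupancies binding probabilities in (0, 1), same length.
#' @param n_domains number of protein domains; sets the starting value and
#'   upper bound for `h`.
#' @return object of class `hill_fit` with fields `h`, `d0`, `rss`, and the
#'   underlying `fit`.
#' @examples
#' D <- exp(seq(log(0.01), log(0.3), length.out = 30))
#' occ <- 1 / (1 + (0.05 / D)^3)
#' fit_hill(D, occ, n_domains = 3)
#' @export
fit_hill <- function(densities, occupancies, n_domains = 1L) {
  if (length(densities) != length(occupancies) || length(densities) < 4L)
    stop("need >= 4 matched (density, occupancy) points", call. = FALSE)
  if (any(!is.finite(densities)) || any(densities <= 0))
    stop("densities must be positive", call. = FALSE)
  if (any(!is.finite(occupancies)) || any(occupancies <= 0) ||
      any(occupancies >= 1))
    stop("occupancies must lie strictly in (0, 1)", call. = FALSE)
  dat <- data.frame(D = densities, occ = occupancies)
  d0_start <- dat$D[which.min(abs(dat$occ - 0.5))]
  fit <- tryCatch(
    minpack.lm::nlsLM(occ ~ 1 / (1 + (D0 / D)^h), data = dat,
                      start = list(h = n_domains, D0 = d0_start),
                      lower = c(1e-3, 1e-9),
                      upper = c(5 * n_domains, 1e3),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("Hill fit did not converge: ", conditionMessage(e),
           sprintf(" [start h = %g, D0 = %g; %d points spanning D = %.3g..%.3g]",
                   n_domains, d0_start, nrow(dat), min(dat$D), max(dat$D)),
           call. = FALSE))
  cf <- coef(fit)
  structure(list(h = unname(cf["h"]), d0 = unname(cf["D0"]),
                 rss = sum(resid(fit)^2), fit = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> h = %.4g, D0 = %.4g sites/nt, rss = %.3g\n",
              x$h, x$d0, x$rss))
  invisible(x)
}

#' Hill coefficient of the density response for an n-domain protein
#'
#' Convenience wrapper running [density_scan()] and [fit_hill()] in one
#' step under one parameter set.
#'
#' @inheritParams density_scan
#' @param ... further arguments passed to [density_scan()].
#' @return a `hill_fit`.
#' @examples
#' hill_cooperativity(1, kd = 50e-6, rna_length_nt = 200, rna_conc = 1e-7)
#' @export
hill_cooperativity <- function(n_domains, kd, rna_length_nt, rna_conc,
                               d_nm = 2, ...) {
  scan <- density_scan(n_domains, kd, rna_length_nt, rna_conc, d_nm, ...)
  fit_hill(scan$density_per_nt, scan$occupancy, n_domains = n_domains)
}
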