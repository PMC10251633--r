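#' Read a protein/RNA model from a JSON config file
#'
#' Config schema (units are human-friendly at the boundary: uM, nt, aa,
#' nm; internally everything is M and nm):
#' \preformatted{
#' {
#'   "protein": {
#'     "domains": [{"kd_uM": 10}, {"kd_uM": 50}],
#'     "geometry": {"type": "rigid",
#'                  "distances_nm": [[0, 2], [2, 0]]}
#'       // or {"type": "flexible", "peptide_linkers_aa": [20],
#'       //     "residual_nm": 0}
#'       // or {"type": "mixed", "gaps": [
#'       //      {"type": "flexible", "aa": 20},
#'       //      {"type": "rigid", "d_nm": 2}]}
#'   },
#'   "rna": {"linkers_nt": [10], "motif_footprint_nt": 0}
#' }
#' }
#'
#' @param path path to a JSON file.
#' @return list with elements `rbp` and `rna`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(cfg$protein) || is.null(cfg$rna))
    stop("config must have 'protein' and 'rna' sections", call. = FALSE)
  dom <- cfg$protein$domains
  kd_uM <- if (is.data.frame(dom)) dom$kd_uM else
    vapply(dom, function(d) d$kd_uM, numeric(1L))
  if (is.null(kd_uM) || any(!is.finite(kd_uM)) || any(kd_uM <= 0))
    stop("protein.domains[].kd_uM must all be positive (micromolar)",
         call. = FALSE)
  n <- length(kd_uM)
  geometry <- NULL
  if (n > 1L) {
    g <- cfg$protein$geometry
    if (is.null(g$type))
      stop("protein.geometry.type is required ('rigid', 'flexible' or ",
           "'mixed')", call. = FALSE)
    geometry <- switch(g$type,
      rigid = {
        d <- g$distances_nm
        if (is.null(d))
          stop("rigid geometry needs distances_nm (nm matrix or per-gap ",
               "vector)", call. = FALSE)
        if (is.list(d)) d <- do.call(rbind, d)
        rigid_geometry(if (is.matrix(d)) d else as.numeric(d), n = n)
      },
      flexible = {
        if (is.null(g$peptide_linkers_aa))
          stop("flexible geometry needs peptide_linkers_aa (one per gap)",
               call. = FALSE)
        flexible_geometry(g$peptide_linkers_aa,
                          if (is.null(g$residual_nm)) 0 else g$residual_nm)
      },
      mixed = {
        if (is.null(g$gaps))
          stop("mixed geometry needs a per-gap 'gaps' list", call. = FALSE)
        gaps <- g$gaps
        if (is.data.frame(gaps))
          gaps <- lapply(seq_len(nrow(gaps)), function(i)
            as.list(gaps[i, , drop = FALSE]))
        gaps <- lapply(gaps, function(gp) gp[!vapply(gp, function(v)
          is.null(v) || (length(v) == 1L && is.na(v)), logical(1L))])
        mixed_geometry(gaps)
      },
      stop("unknown geometry type: ", g$type, call. = FALSE))
  }
  linkers <- cfg$rna$linkers_nt
  if (is.null(linkers)) linkers <- numeric(0)
  fp <- cfg$rna$motif_footprint_nt
  if (is.null(fp)) fp <- 0
  rna <- rna_target(linkers, fp)
  rbp <- rbp_model(kd = kd_uM * 1e-6, geometry = geometry)
  if (rbp$n != rna$n)
    stop(sprintf("config inconsistent: %d domains but %d RNA sites",
                 rbp$n, rna$n), call. = FALSE)
  list(rbp = rbp, rna = rna)
}

#' Write a results table as TSV with a `#`-prefixed provenance header
#'
#' Every CLI output starts with header lines recording the package version,
#' the seed and the chain constants in force, so that a run can be
#' reproduced from its own output.
#'
#' @param df data.frame to write.
#' @param path output file, or `""` for standard output.
#' @param seed integer seed to echo.
#' @param constants a [chain_constants()] table to echo.
#' @param extra named character vector of extra header fields.
#' @return invisibly, `path`.
#' @export
write_tsv_report <- function(df, path, seed = NA_integer_,
                             constants = chain_constants(),
                             extra = character(0)) {
  con <- if (identical(path, "")) stdout() else file(path, "w")
  if (!identical(path, "")) on.exit(close(con))
  version <- as.character(utils::packageVersion("coopbind"))
  writeLines(c(sprintf("# coopbind %s", version),
               sprintf("# seed: %s", seed),
               sprintf("# constants: %s", format_constants(constants)),
               if (length(extra))
                 sprintf("# %s: %s", names(extra), unname(extra))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
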