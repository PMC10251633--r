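#' Load multi-domain protein fixtures for the validation pipeline
#'
#' The package ships a seven-protein fixture table
#' (`inst/extdata/rbp_fixtures_synthetic.json`) mirroring the topologies of
#' well-studied multi-domain RBPs: ZBP1 (rigid KH didomain), hnRNP A1
#' (rigid tandem RRMs), PTB (two terminal RRMs), IMP3 (two KH didomain
#' pairs joined by a flexible peptide linker), IMP1 (rigid KH didomain),
#' U2AF65 (flexibly linked tandem RRMs, measured against three RNA linker
#' variants) and KSRP (four KH domains with the middle two forming a rigid
#' unit). The numeric values in the shipped table are a SYNTHETIC stand-in:
#' literature-scale domain affinities, geometries and full-length
#' "measurements" constructed for exercising the pipeline, not transcribed
#' experimental data. Users supply their own measured parameters through
#' `path`.
#'
#' Every fixture must carry a non-empty `source_note`; the loader refuses
#' tables whose provenance is not stated.
#'
#' @param path JSON fixture file; defaults to the shipped synthetic table.
#' @return list of `protein_fixture` objects.
#' @export
builtin_fixtures <- function(path = system.file("extdata",
                                                "rbp_fixtures_synthetic.json",
                                                package = "coopbind")) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  proteins <- raw$proteins
  if (is.null(proteins) || length(proteins) < 1L)
    stop("fixture file has no 'proteins' entries", call. = FALSE)
  lapply(proteins, as_protein_fixture)
}

as_protein_fixture <- function(p) {
  need <- function(field) {
    if (is.null(p[[field]]))
      stop("fixture '", if (is.null(p$name)) "?" else p$name,
           "' is missing field '", field, "'", call. = FALSE)
    p[[field]]
  }
  name <- need("name")
  note <- need("source_note")
  if (!nzchar(trimws(note)))
    stop("fixture '", name, "' has an empty source_note; refusing ",
         "unverified parameters", call. = FALSE)
  kd_uM <- unlist(need("domain_kd_uM"))
  if (any(!is.finite(kd_uM)) || any(kd_uM <= 0))
    stop("fixture '", name, "': all domain Kd must be positive",
         call. = FALSE)
  n <- length(kd_uM)
  disabled <- if (is.null(p$disabled)) rep(FALSE, n) else
    rep_len(as.logical(unlist(p$disabled)), n)
  g <- need("geometry")
  geometry <- if (n == 1L) NULL else switch(g$type,
    rigid = {
      d <- g$distances_nm
      if (is.list(d) && any(lengths(d) > 1L))
        d <- do.call(rbind, lapply(d, unlist))   # full matrix, row-wise
      else
        d <- unlist(d)                           # per-gap vector or scalar
      rigid_geometry(d, n = n)
    },
    flexible = flexible_geometry(unlist(g$peptide_linkers_aa),
                                 if (is.null(g$residual_nm)) 0
                                 else unlist(g$residual_nm)),
    mixed = mixed_geometry(g$gaps),
    stop("fixture '", name, "': unknown geometry type ", g$type,
         call. = FALSE))
  # one or several RNA linker variants, each with its measured full Kd
  if (!is.null(p$rna_linker_variants_nt)) {
    variants <- lapply(p$rna_linker_variants_nt, unlist)
    measured_uM <- unlist(need("measured_full_kd_uM"))
    if (length(measured_uM) != length(variants))
      stop("fixture '", name, "': one measured Kd per RNA variant required",
           call. = FALSE)
  } else {
    variants <- list(unlist(need("rna_linkers_nt")))
    measured_uM <- unlist(need("measured_full_kd_uM"))
    if (length(measured_uM) != 1L)
      stop("fixture '", name, "': a single measured Kd expected",
           call. = FALSE)
  }
  if (any(!is.finite(measured_uM)) || any(measured_uM <= 0))
    stop("fixture '", name, "': measured Kd must be positive", call. = FALSE)
  structure(list(name = name,
                 kd = kd_uM * 1e-6,
                 disabled = disabled,
                 geometry = geometry,
                 rna_variants_nt = variants,
                 measured_kd = measured_uM * 1e-6,
                 pdb_id = if (is.null(p$pdb_id)) NA_character_ else p$pdb_id,
                 source_note = note),
            class = "protein_fixture")
}

#' @export
print.protein_fixture <- function(x, ...) {
  cat(sprintf("<protein_fixture> %s: %d domain(s), Kd = %s uM, %d RNA variant(s)\n",
              x$name, length(x$kd), paste(signif(x$kd * 1e6, 3),
                                          collapse = "/"),
              length(x$rna_variants_nt)))
  invisible(x)
}

# exact avidity restricted to configurations that avoid disabled sites
kav_with_disabled <- function(rbp, rna, disabled,
                              constants = chain_constants()) {
  configs <- enumerate_configurations(rbp$n)[-1L]
  keep <- vapply(configs, function(cf)
    !any(disabled[config_sites(cf)]), logical(1L))
  sum(vapply(configs[keep], function(cf)
    configuration_weight(rbp, rna, cf, constants, warn = FALSE),
    numeric(1L)))
}

#' Predict the full-length dissociation constant of a fixture protein
#'
#' Runs the thermodynamic model with no free parameters: the exact avidity
#' is computed from the fixture's individual-domain affinities, geometry
#' and RNA linker lengths; `predicted_kd = 1 / K_av`. The independent-
#' binding limit (`1 / sum(Ka_i)`, the avidity of infinitely separated
#' sites) is reported alongside, and the symmetric fold error
#' `max(pred/meas, meas/pred)` against the fixture's measured value.
#' Fixtures with several RNA linker variants yield one row per variant.
#'
#' @param fixture a `protein_fixture` from [builtin_fixtures()].
#' @param constants a [chain_constants()] table.
#' @return `data.frame` with columns `name`, `variant`, `predicted_kd`,
#'   `measured_kd`, `independent_limit_kd` (all in M) and `fold_error`.
#' @export
predict_full_length <- function(fixture, constants = chain_constants()) {
  stopifnot(inherits(fixture, "protein_fixture"))
  n <- length(fixture$kd)
  if (n > 1L && is.null(fixture$geometry))
    stop("fixture '", fixture$name, "' is missing its geometry",
         call. = FALSE)
  rbp <- rbp_model(kd = fixture$kd, geometry = fixture$geometry)
  enabled_ka <- rbp$ka[!fixture$disabled]
  independent <- 1 / sum(enabled_ka)
  rows <- lapply(seq_along(fixture$rna_variants_nt), function(v) {
    rna <- rna_target(fixture$rna_variants_nt[[v]])
    if (rna$n != n)
      stop("fixture '", fixture$name, "': RNA variant ", v, " has ",
           rna$n, " sites for ", n, " domains", call. = FALSE)
    kav <- kav_with_disabled(rbp, rna, fixture$disabled, constants)
    pred <- 1 / kav
    meas <- fixture$measured_kd[v]
    data.frame(name = fixture$name, variant = v, predicted_kd = pred,
               measured_kd = meas, independent_limit_kd = independent,
               fold_error = max(pred / meas, meas / pred))
  })
  do.call(rbind, rows)
}

#' Combine prediction rows into a comparison report
#'
#' @param rows `data.frame` of rows from [predict_full_length()] (or a
#'   list of such data.frames), at least one row.
#' @param path optional TSV output path (written with
#'   [write_tsv_report()]).
#' @param constants constants to echo into the TSV header.
#' @return the combined `data.frame`, with attributes `max_fold_error` and
#'   `median_fold_error`.
#' @export
compare_table <- function(rows, path = NULL,
                          constants = chain_constants()) {
  if (is.list(rows) && !is.data.frame(rows)) rows <- do.call(rbind, rows)
  if (!is.data.frame(rows) || nrow(rows) < 1L)
    stop("need at least one comparison row", call. = FALSE)
  attr(rows, "max_fold_error") <- max(rows$fold_error)
  attr(rows, "median_fold_error") <- stats::median(rows$fold_error)
  if (!is.null(path))
    write_tsv_report(rows, path, constants = constants,
                     extra = c(max_fold_error =
                                 sprintf("%.4g", max(rows$fold_error)),
                               median_fold_error =
                                 sprintf("%.4g",
                                         stats::median(rows$fold_error))))
  rows
}

#' Run the full validation pipeline over all fixtures
#'
#' @inheritParams builtin_fixtures
#' @inheritParams compare_table
#' @return see [compare_table()].
#' @export
run_validation <- function(path = NULL, fixtures = builtin_fixtures(),
                           constants = chain_constants()) {
  rows <- lapply(fixtures, predict_full_length, constants = constants)
  compare_table(rows, path = path, constants = constants)
}
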