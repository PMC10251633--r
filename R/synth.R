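# run code under a local, restorable RNG state
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a random synthetic protein/RNA model
#'
#' Draws an n-domain protein and matching n-site RNA in the regime typical
#' of sequence-specific RBPs: per-domain Kd log-uniform between 1 uM and
#' 1 mM, RNA linkers uniform between 5 and 40 nt, consecutive inter-domain
#' distances uniform between 1 and 5 nm (expanded to a collinear rigid
#' distance matrix). Deterministic per seed; the caller's RNG state is not
#' disturbed.
#'
#' @param n number of domains/sites, 1 to 8.
#' @param seed integer seed.
#' @return list with elements `rbp` ([rbp_model()]) and `rna`
#'   ([rna_target()]).
#' @examples
#' m <- generate_synthetic_model(3, seed = 7)
#' m$rbp; m$rna
#' @export
generate_synthetic_model <- function(n, seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 1L || n > 8L ||
      n != round(n))
    stop("n must be an integer between 1 and 8", call. = FALSE)
  n <- as.integer(n)
  with_local_seed(seed, {
    kd <- 10^runif(n, log10(1e-6), log10(1e-3))
    geometry <- NULL
    linkers <- numeric(0)
    if (n > 1L) {
      linkers <- round(runif(n - 1L, 5, 40))
      d_gaps <- runif(n - 1L, 1, 5)
      geometry <- rigid_geometry(d_gaps, n = n)
    }
    list(rbp = rbp_model(kd = kd, geometry = geometry),
         rna = rna_target(linkers))
  })
}
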