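# Reproducible hypothetical variants for property testing.  The draw
# ranges bracket the measured panel (turnover numbers of a few to a couple
# of hundred per minute, Michaelis constants from sub-uM to tens of uM,
# IC50 values from single-digit nM to tens of uM), so the invariants are
# exercised well beyond the shipped tables.

#' Generate a reproducible hypothetical enzyme variant
#'
#' Draws `kcat`, `KM` and per-drug IC50 values log-uniformly within the
#' given ranges, a free-energy shift uniformly, and an ATP-site flag with
#' probability 1/4, all under a temporary RNG state so the global RNG is
#' untouched and the same seed always yields the same variant.
#'
#' @param seed integer seed.
#' @param ranges list with elements `kcat`, `KM`, `ic50` (each a length-2
#'   positive range) and `ddG` (length-2 range, kcal/mol).
#' @param drugs drug names to draw IC50 values for.
#' @return an [enzyme_variant()] named `synthetic-<seed>`.
#' @export
synthesize_variant <- function(seed,
                               ranges = list(kcat = c(2, 200),
                                             KM = c(0.5, 25),
                                             ic50 = c(1, 1e4),
                                             ddG = c(-3, 1)),
                               drugs = c("imatinib", "ponatinib", "dasatinib")) {
  stopifnot(all(ranges$kcat > 0), all(ranges$KM > 0), all(ranges$ic50 > 0))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  log_unif <- function(r) exp(stats::runif(1, log(r[1]), log(r[2])))
  ic50 <- vapply(drugs, function(d) log_unif(ranges$ic50), numeric(1))
  enzyme_variant(paste0("synthetic-", seed),
                 kcat = log_unif(ranges$kcat),
                 KM = log_unif(ranges$KM),
                 ic50 = ic50,
                 ddG = stats::runif(1, ranges$ddG[1], ranges$ddG[2]),
                 atp_site_mutant = stats::runif(1) < 0.25)
}
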