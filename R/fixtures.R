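# Packaged data tables (measured catalytic constants, IC50 values,
# residence times, free-energy shifts, pharmacokinetic parameters,
# resistance annotations) plus the published derived-constant tables used
# as reference in validation, with a machine-readable erratum overlay.

.fixture_files <- c(
  kinetics = "kinetic_constants.tsv",
  residence = "residence_times.tsv",
  free_energy = "free_energy.tsv",
  pk = "pk_parameters.tsv",
  annotations = "resistance_annotations.tsv",
  ref_inhibitor = "reference_inhibitor_rates.tsv",
  ref_substrate = "reference_substrate_rates.tsv",
  errata = "errata.tsv")

.fixture_columns <- list(
  kinetics = c("variant", "kcat_per_min", "KM_uM", "ic50_imatinib_nM",
               "ic50_ponatinib_nM", "ic50_dasatinib_nM", "atp_site"),
  residence = c("drug", "binding_mode", "tR_min", "koffR_per_min"),
  free_energy = c("variant", "dG_active_kcal_per_mol", "dG_active_se",
                  "dG_inactive_kcal_per_mol", "dG_inactive_se",
                  "ddG_kcal_per_mol", "ddG_se"),
  pk = c("quantity", "units", "imatinib", "ponatinib", "dasatinib"),
  annotations = c("variant", "imatinib", "ponatinib", "dasatinib"),
  ref_inhibitor = c("variant", "RD_imatinib_nM", "RD_ponatinib_nM",
                    "RD_dasatinib_nM", "koffR_imatinib_per_min",
                    "koffR_ponatinib_per_min", "koffR_dasatinib_per_min",
                    "konR_imatinib_per_nM_min", "konR_ponatinib_per_nM_min",
                    "konR_dasatinib_per_nM_min"),
  ref_substrate = c("variant", "koffS_per_min", "konS_per_uM_min"),
  errata = c("id", "table", "action", "detail"))

#' Load the packaged data tables
#'
#' Reads the delimited-text tables shipped with the package (or from a
#' directory with identically named files), validates their headers, and
#' applies the documented erratum corrections to the reference tables:
#' the decimal-shift misprint in one dissociation-constant cell and the
#' transposed on-rate columns of the two inactive-state binders.  Raw
#' printed values remain available under `$raw`.
#'
#' @param path directory containing the tables; default: the packaged
#'   copies under `extdata`.
#' @return an object of class `fixture_bundle`.
#' @export
load_fixtures <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", package = "ablresist", mustWork = TRUE)
  raw <- list()
  for (key in names(.fixture_files)) {
    file <- file.path(path, .fixture_files[[key]])
    if (!file.exists(file)) stop("fixture file missing: ", file)
    tab <- utils::read.delim(file, colClasses = "character",
                             check.names = FALSE)
    missing <- setdiff(.fixture_columns[[key]], names(tab))
    if (length(missing))
      stop("fixture table '", key, "' is missing column(s): ",
           paste(missing, collapse = ", "))
    raw[[key]] <- tab
  }
  bundle <- list(raw = raw)
  num <- function(x) as.numeric(x)

  k <- raw$kinetics
  bundle$kinetics <- data.frame(
    variant = k$variant, kcat_per_min = num(k$kcat_per_min),
    KM_uM = num(k$KM_uM), ic50_imatinib_nM = num(k$ic50_imatinib_nM),
    ic50_ponatinib_nM = num(k$ic50_ponatinib_nM),
    ic50_dasatinib_nM = num(k$ic50_dasatinib_nM),
    atp_site = toupper(k$atp_site) == "TRUE", stringsAsFactors = FALSE)

  r <- raw$residence
  bundle$residence <- data.frame(
    drug = r$drug, binding_mode = r$binding_mode, tR_min = num(r$tR_min),
    koffR_per_min = num(r$koffR_per_min), stringsAsFactors = FALSE)

  g <- raw$free_energy
  bundle$free_energy <- data.frame(
    variant = g$variant, ddG_kcal_per_mol = num(g$ddG_kcal_per_mol),
    ddG_se = num(g$ddG_se), stringsAsFactors = FALSE)

  p <- raw$pk
  pk_num <- as.data.frame(lapply(p[c("imatinib", "ponatinib", "dasatinib")],
                                 num))
  rownames(pk_num) <- p$quantity
  bundle$pk <- pk_num

  bundle$annotations <- raw$annotations

  ref <- raw$ref_inhibitor
  ref_num <- data.frame(variant = ref$variant, stringsAsFactors = FALSE)
  for (cn in setdiff(names(ref), "variant")) ref_num[[cn]] <- num(ref[[cn]])
  bundle$ref_inhibitor_raw <- ref_num
  bundle$ref_inhibitor <- apply_errata(ref_num, raw$errata)

  rs <- raw$ref_substrate
  bundle$ref_substrate <- data.frame(
    variant = rs$variant, koffS_per_min = num(rs$koffS_per_min),
    konS_per_uM_min = num(rs$konS_per_uM_min), stringsAsFactors = FALSE)

  bundle$errata <- raw$errata
  bundle$provenance <- c(
    kinetics = "measured catalytic constants and IC50 values (literature-compiled)",
    residence = "measured wild-type inhibitor residence times and off-rates",
    free_energy = "free-energy perturbation results, consumed as constants",
    pk = "published pharmacokinetic parameters and derived curve constants",
    annotations = "clinical resistance associations per variant and drug",
    ref_inhibitor = "published derived dissociation/binding constants (validation reference)",
    ref_substrate = "published derived substrate rate constants (validation reference)")
  structure(bundle, class = "fixture_bundle")
}

apply_errata <- function(ref, errata) {
  for (i in seq_len(nrow(errata))) {
    id <- errata$id[i]
    if (id == "rd_e255k_imatinib_decimal") {
      sel <- ref$variant == "E255K"
      ref$RD_imatinib_nM[sel] <- ref$RD_imatinib_nM[sel] / 10
    } else if (id == "konr_imatinib_ponatinib_transposed") {
      tmp <- ref$konR_imatinib_per_nM_min
      ref$konR_imatinib_per_nM_min <- ref$konR_ponatinib_per_nM_min
      ref$konR_ponatinib_per_nM_min <- tmp
    }
    # "note" actions document inconsistencies without editing cells
  }
  ref
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("<fixture_bundle> ", nrow(x$kinetics), " variants, ",
      nrow(x$residence), " drugs; ", nrow(x$errata),
      " documented errata\n", sep = "")
  invisible(x)
}

#' Write a fixture bundle back to delimited text
#'
#' Writes the raw (uncorrected) tables with the same formatting they were
#' read with, so that a load/write cycle is byte-identical.
#'
#' @param bundle a [load_fixtures()] bundle.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_fixtures <- function(bundle, path) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (key in names(.fixture_files)) {
    utils::write.table(bundle$raw[[key]],
                       file.path(path, .fixture_files[[key]]),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Enzyme variant from a fixture bundle
#'
#' @param bundle a [load_fixtures()] bundle.
#' @param name variant name as it appears in the tables.
#' @return an [enzyme_variant()].
#' @export
bundle_variant <- function(bundle, name) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  k <- bundle$kinetics[bundle$kinetics$variant == name, ]
  if (nrow(k) != 1L) stop("unknown variant '", name, "'")
  g <- bundle$free_energy[bundle$free_energy$variant == name, ]
  ddG <- if (nrow(g) == 1L) g$ddG_kcal_per_mol else NA_real_
  enzyme_variant(name, kcat = k$kcat_per_min, KM = k$KM_uM,
                 ic50 = c(imatinib = k$ic50_imatinib_nM,
                          ponatinib = k$ic50_ponatinib_nM,
                          dasatinib = k$ic50_dasatinib_nM),
                 ddG = ddG, atp_site_mutant = k$atp_site)
}

#' Drug specifications from a fixture bundle
#'
#' @param bundle a [load_fixtures()] bundle.
#' @return named list of [drug_spec()] objects with raw and printed
#'   pharmacokinetics attached.
#' @export
bundle_drugs <- function(bundle) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  out <- list()
  for (i in seq_len(nrow(bundle$residence))) {
    row <- bundle$residence[i, ]
    pkc <- bundle$pk[[row$drug]]
    names(pkc) <- rownames(bundle$pk)
    raw <- pk_inputs(F_bio = pkc[["F"]], D_mass = pkc[["dose"]],
                     M = pkc[["molar_mass"]], ka = pkc[["ka"]],
                     t_half_e = pkc[["t_half_e"]], Vd = pkc[["Vd"]],
                     tau = pkc[["tau"]])
    printed <- pk_constants_printed(Gamma = pkc[["Gamma"]],
                                    alpha = pkc[["alpha"]],
                                    epsilon = pkc[["epsilon"]],
                                    ka = pkc[["ka"]], ke = pkc[["ke"]],
                                    tau = pkc[["tau"]])
    out[[row$drug]] <- drug_spec(row$drug, row$binding_mode,
                                 tR = row$tR_min, koffR = row$koffR_per_min,
                                 pk = raw, pk_printed = printed)
  }
  out
}

#' Concentration-curve constants for a drug in a bundle
#'
#' @param bundle a [load_fixtures()] bundle.
#' @param drug drug name.
#' @param mode `"printed"` (published constants, the simulation default) or
#'   `"derived"` (recomputed from the raw inputs).
#' @return a `pk_constants` object.
#' @export
drug_pk_constants <- function(bundle, drug, mode = c("printed", "derived")) {
  mode <- match.arg(mode)
  d <- bundle_drugs(bundle)[[drug]]
  if (is.null(d)) stop("unknown drug '", drug, "'")
  if (mode == "printed") d$pk_printed else pk_constants(d$pk)
}

#' Names of the variants with complete simulation inputs
#'
#' @param bundle a [load_fixtures()] bundle.
#' @return character vector: the wild type plus the mutants that have
#'   free-energy data (the simulated set).
#' @export
simulated_variant_names <- function(bundle) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  intersect(bundle$kinetics$variant, bundle$free_energy$variant)
}

#' Resistance annotation for a variant and drug
#'
#' @param bundle a [load_fixtures()] bundle.
#' @param variant,drug names.
#' @return `"resistant"`, `"compound_only"` or `"sensitive"`.
#' @export
bundle_annotation <- function(bundle, variant, drug) {
  a <- bundle$annotations[bundle$annotations$variant == variant, ]
  if (nrow(a) != 1L || is.null(a[[drug]]))
    stop("no annotation for ", variant, " x ", drug)
  a[[drug]]
}
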