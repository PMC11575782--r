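# Rate-constant derivations: from measurable quantities (residence time,
# IC50, kcat, KM, free-energy shifts) to the microscopic rate constants of
# the four-state model.  Internal unit system: inhibitor concentrations in
# nM, substrate/enzyme concentrations in uM, time in minutes.

# molar gas constant in kcal/(mol K)
.R_KCAL <- 1.9872e-3

#' Convert a residence time to an unbinding rate constant
#'
#' The mean bound lifetime of an inhibitor is the reciprocal of its
#' first-order unbinding rate constant.
#'
#' @param tR residence time, min.
#' @return off-rate constant, min^-1.
#' @examples
#' residence_to_koff(17)    # imatinib, ~0.059
#' residence_to_koff(205)   # ponatinib, ~0.00488
#' @export
residence_to_koff <- function(tR) {
  if (any(!is.finite(tR)) || any(tR <= 0))
    stop("residence time must be finite and > 0")
  1 / tR
}

#' Boltzmann factor of the active-inactive free-energy gap
#'
#' @param thermo a [thermo_config()].
#' @param ddG mutation shift of the gap, kcal/mol (0 for the wild type).
#' @return dimensionless factor: exactly 1 under the `effective_unity`
#'   convention; `exp(-(dG_WT + ddG)/(R T))` under `per_mole_RT`.
#' @export
thermo_factor <- function(thermo, ddG = 0) {
  stopifnot(inherits(thermo, "thermo_config"))
  if (thermo$convention == "effective_unity") return(1)
  if (is.na(ddG))
    stop("per_mole_RT convention needs a ddG value for this variant")
  exp(-(thermo$dG_WT + ddG) / (.R_KCAL * thermo$temperature))
}

#' Combined statistical weight of the uninhibited bound-competent states
#'
#' The weight of the free active state plus the substrate-bound state,
#' relative to the free inactive state: `factor * (1 + S/KM)`.  Adding 1
#' (the inactive-state weight) gives the total uninhibited weight, which is
#' the denominator in the IC50-to-dissociation-constant conversion.
#'
#' @param factor thermodynamic factor, see [thermo_factor()].
#' @param S substrate concentration, uM.
#' @param KM Michaelis constant, uM.
#' @return dimensionless weight.
#' @export
uninhibited_weight <- function(factor, S, KM) {
  if (any(KM <= 0)) stop("KM must be > 0")
  if (any(S < 0)) stop("S must be >= 0")
  factor * (1 + S / KM)
}

#' Convert an IC50 to an inhibitor dissociation constant
#'
#' Equating the half-inhibited product-formation rate with the
#' quasi-equilibrium rate expression gives, for an inactive-state binder,
#' `RD = IC50 / (weight + 1)` and, for an active-state binder,
#' `RD = IC50 * factor / (weight + 1)`, with `weight` from
#' [uninhibited_weight()].
#'
#' @param ic50 IC50, nM.
#' @param binding_mode `"inactive_binder"` or `"active_binder"`.
#' @param weight output of [uninhibited_weight()].
#' @param factor thermodynamic factor.
#' @return dissociation constant, nM.
#' @examples
#' w <- uninhibited_weight(1, 10, 17)
#' ic50_to_kd(527, "inactive_binder", w)  # wild-type imatinib, 203.6 nM
#' ic50_to_kd(1.8, "active_binder", w)    # wild-type dasatinib, 0.695 nM
#' @export
ic50_to_kd <- function(ic50, binding_mode = c("inactive_binder", "active_binder"),
                       weight, factor = 1) {
  binding_mode <- match.arg(binding_mode)
  if (any(ic50 <= 0)) stop("ic50 must be > 0")
  if (any(weight < 0)) stop("weight must be >= 0")
  if (binding_mode == "inactive_binder") ic50 / (weight + 1)
  else ic50 * factor / (weight + 1)
}

#' On-rate constant from off-rate and dissociation constant
#'
#' @param koffR off-rate constant, min^-1.
#' @param RD dissociation constant, nM.
#' @return on-rate constant, nM^-1 min^-1.
#' @export
kon_from_koff <- function(koffR, RD) {
  if (any(koffR <= 0)) stop("koffR must be > 0")
  if (any(RD <= 0)) stop("RD must be > 0")
  koffR / RD
}

#' Substrate binding and unbinding rate constants
#'
#' Splits the Michaelis constant `KM = (kcat + koffS)/konS` into its two
#' unknowns using fitness-based rules.  For the wild type the enzyme is
#' assumed more likely to catalyse than to release substrate, so
#' `koffS = kcat/2` and `konS` follows from KM.  For a mutant the opposite
#' is assumed (`koffS = 2 kcat`, hence `konS = 3 kcat / KM`), unless that
#' candidate on-rate would fall below the wild-type on-rate - an untreated
#' mutant must still compete with the wild type - in which case
#' `konS = konS_WT` and `koffS = KM * konS_WT - kcat`.
#'
#' @param kcat turnover number, min^-1.
#' @param KM Michaelis constant, uM.
#' @param konS_WT wild-type substrate on-rate constant, uM^-1 min^-1.
#'   Leave `NULL` to apply the wild-type rule.
#' @return an object of class `substrate_rates` with elements `konS`
#'   (uM^-1 min^-1), `koffS` (min^-1) and `branch`.
#' @examples
#' substrate_rates(66, 17)                      # wild type: koffS 33, konS 5.82
#' wt <- substrate_rates(66, 17)
#' substrate_rates(175.2, 14.3, wt$konS)        # G250E: mutant branch
#' substrate_rates(6.8, 22.1, wt$konS)          # E255V: fallback branch
#' @export
substrate_rates <- function(kcat, KM, konS_WT = NULL) {
  stopifnot(kcat > 0, KM > 0)
  if (is.null(konS_WT)) {
    koffS <- kcat / 2
    konS <- (kcat + koffS) / KM
    branch <- "wild_type"
  } else {
    stopifnot(konS_WT > 0)
    candidate <- 3 * kcat / KM
    if (candidate >= konS_WT) {
      koffS <- 2 * kcat
      konS <- candidate
      branch <- "mutant"
    } else {
      konS <- konS_WT
      koffS <- KM * konS_WT - kcat
      branch <- "mutant_fallback"
      if (koffS <= 0)
        stop("inconsistent inputs: fallback substrate off-rate is not positive ",
             "(KM * konS_WT <= kcat)")
    }
  }
  structure(list(konS = konS, koffS = koffS, branch = branch),
            class = "substrate_rates")
}

#' Inhibitor rate constants for a variant, inherited from the wild type
#'
#' Inactive-state binders keep the wild-type off-rate across variants (the
#' bound complex is assumed to interact as in the wild type), so the
#' on-rate follows from the variant dissociation constant.  Active-state
#' binders keep the wild-type on-rate, except for ATP-site variants, whose
#' on-rate is scaled by the same factor as their substrate on-rate (binding
#' at the active site is assumed to change like ATP/substrate binding);
#' the off-rate then follows from the dissociation constant.
#'
#' @param binding_mode `"inactive_binder"` or `"active_binder"`.
#' @param wt_rates wild-type `inhibitor_rates` (list with `RD`, `konR`,
#'   `koffR`).
#' @param RD variant dissociation constant, nM.
#' @param konS_ratio variant-to-wild-type substrate on-rate ratio.
#' @param atp_site_mutant logical, see [enzyme_variant()].
#' @return an object of class `inhibitor_rates`: `RD` (nM), `konR`
#'   (nM^-1 min^-1), `koffR` (min^-1), satisfying `RD * konR == koffR`.
#' @export
inhibitor_rates <- function(binding_mode = c("inactive_binder", "active_binder"),
                            wt_rates, RD, konS_ratio = 1,
                            atp_site_mutant = FALSE) {
  binding_mode <- match.arg(binding_mode)
  stopifnot(RD > 0, konS_ratio > 0)
  if (binding_mode == "inactive_binder") {
    koffR <- wt_rates$koffR
    konR <- koffR / RD
  } else {
    konR <- if (atp_site_mutant) wt_rates$konR * konS_ratio else wt_rates$konR
    koffR <- konR * RD
  }
  structure(list(RD = RD, konR = konR, koffR = koffR),
            class = "inhibitor_rates")
}

#' Conformational transition rate constants
#'
#' All variants switch between the active and inactive conformation at
#' 60 min^-1 in both directions, except G250E, whose larger stabilisation
#' of the inactive state slows the switch slightly (55 min^-1).  Equal
#' forward and backward rates are consistent with a unit thermodynamic
#' factor for the conformational equilibrium.
#'
#' @param variant_name variant identifier.
#' @return named numeric vector `c(ktransA =, ktransI =)`, min^-1.
#' @export
conformational_rates <- function(variant_name) {
  k <- if (identical(variant_name, "G250E")) 55 else 60
  c(ktransA = k, ktransI = k)
}

#' Mutant active-inactive free-energy difference
#'
#' @param dG_WT wild-type gap, kcal/mol.
#' @param ddG mutation shift, kcal/mol.
#' @return mutant gap, kcal/mol.
#' @export
mutant_dG <- function(dG_WT, ddG) dG_WT + ddG

#' Assemble the complete rate-constant set for one variant and drug
#'
#' Runs every derivation rule in order: thermodynamic factor, uninhibited
#' weight, IC50 to dissociation constant, substrate rates (wild-type or
#' mutant branch), inhibitor rates inherited from the wild type, and
#' conformational rates.  For a mutant, the wild-type parameter set for the
#' same drug must be supplied (or is derived on the fly from `wt_variant`).
#'
#' @param variant an [enzyme_variant()].
#' @param drug a [drug_spec()].
#' @param thermo a [thermo_config()].
#' @param wt_reference wild-type `variant_drug_parameters` for the same
#'   drug, or `NULL` when `variant` itself is the wild type.
#' @return an object of class `variant_drug_parameters`.
#' @examples
#' wt <- enzyme_variant("Wild-type", 66, 17,
#'                      c(imatinib = 527, ponatinib = 2.1, dasatinib = 1.8))
#' ima <- drug_spec("imatinib", "inactive_binder", tR = 17, koffR = 0.059)
#' p <- build_parameter_set(wt, ima)
#' p$inhibitor$RD   # 203.6 nM
#' @export
build_parameter_set <- function(variant, drug, thermo = thermo_config(),
                                wt_reference = NULL) {
  stopifnot(inherits(variant, "enzyme_variant"), inherits(drug, "drug_spec"),
            inherits(thermo, "thermo_config"))
  ic50 <- unname(variant$ic50[drug$name])
  if (length(ic50) != 1L || is.na(ic50))
    stop("variant '", variant$name, "' has no IC50 for drug '", drug$name, "'")
  f <- thermo_factor(thermo, variant$ddG)
  w <- uninhibited_weight(f, thermo$S, variant$KM)
  RD <- ic50_to_kd(ic50, drug$binding_mode, w, f)
  if (is.null(wt_reference)) {
    sub <- substrate_rates(variant$kcat, variant$KM)
    koffR <- drug$koffR
    inh <- structure(list(RD = RD, konR = kon_from_koff(koffR, RD),
                          koffR = koffR),
                     class = "inhibitor_rates")
  } else {
    stopifnot(inherits(wt_reference, "variant_drug_parameters"))
    if (!identical(wt_reference$drug$name, drug$name))
      stop("wt_reference was derived for drug '", wt_reference$drug$name,
           "', not '", drug$name, "'")
    sub <- substrate_rates(variant$kcat, variant$KM,
                           konS_WT = wt_reference$substrate$konS)
    inh <- inhibitor_rates(drug$binding_mode, wt_reference$inhibitor, RD,
                           konS_ratio = sub$konS / wt_reference$substrate$konS,
                           atp_site_mutant = variant$atp_site_mutant)
  }
  kt <- conformational_rates(variant$name)
  structure(list(variant = variant, drug = drug, thermo = thermo,
                 substrate = sub, inhibitor = inh,
                 ktransA = unname(kt["ktransA"]),
                 ktransI = unname(kt["ktransI"]),
                 factor = f, ic50 = ic50),
            class = "variant_drug_parameters")
}

#' @export
print.variant_drug_parameters <- function(x, ...) {
  cat("<variant_drug_parameters> ", x$variant$name, " x ", x$drug$name,
      " (", x$drug$binding_mode, ")\n", sep = "")
  cat(sprintf("  substrate: konS %.4g uM^-1 min^-1, koffS %.4g min^-1 (%s)\n",
              x$substrate$konS, x$substrate$koffS, x$substrate$branch))
  cat(sprintf("  inhibitor: RD %.4g nM, konR %.4g nM^-1 min^-1, koffR %.4g min^-1\n",
              x$inhibitor$RD, x$inhibitor$konR, x$inhibitor$koffR))
  cat(sprintf("  ktransA = ktransI = %g min^-1, thermodynamic factor %g\n",
              x$ktransA, x$factor))
  invisible(x)
}

#' Derive rate constants for every variant and drug in a fixture bundle
#'
#' Reproduces the published derived-constant tables from the raw measured
#' inputs.  Returns one row per variant x drug with the dissociation
#' constant, binding rates and substrate rates.
#'
#' @param bundle a [load_fixtures()] bundle.
#' @param thermo a [thermo_config()].
#' @param variants character vector of variant names (default: variants with
#'   full kinetic data, i.e. the simulated set).
#' @return data.frame with columns `variant`, `drug`, `RD_nM`,
#'   `konR_per_nM_min`, `koffR_per_min`, `konS_per_uM_min`, `koffS_per_min`,
#'   `branch`.
#' @export
derive_parameter_table <- function(bundle, thermo = thermo_config(),
                                   variants = NULL) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  drugs <- bundle_drugs(bundle)
  if (is.null(variants)) variants <- simulated_variant_names(bundle)
  rows <- list()
  for (d in drugs) {
    wt <- build_parameter_set(bundle_variant(bundle, "Wild-type"), d, thermo)
    for (v in variants) {
      p <- if (v == "Wild-type") wt else
        build_parameter_set(bundle_variant(bundle, v), d, thermo, wt)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, drug = d$name,
        RD_nM = p$inhibitor$RD,
        konR_per_nM_min = p$inhibitor$konR,
        koffR_per_min = p$inhibitor$koffR,
        konS_per_uM_min = p$substrate$konS,
        koffS_per_min = p$substrate$koffS,
        branch = p$substrate$branch,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
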