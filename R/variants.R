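#' Define an enzyme variant
#'
#' Bundles the measured quantities that characterise one form of the Abl1
#' kinase (wild type or mutant): catalytic turnover, Michaelis constant,
#' per-drug IC50 values, the active/inactive free-energy shift of the
#' mutation, and whether the mutated residue forms or borders the ATP
#' binding site (which changes how active-state binder on-rates are
#' inherited from the wild type).
#'
#' @param name variant identifier, e.g. `"Wild-type"` or `"E255K"`.
#' @param kcat catalytic turnover number, min^-1.
#' @param KM Michaelis constant, uM.
#' @param ic50 named numeric vector of IC50 values in nM, one per drug name.
#' @param ddG free-energy shift of the active-inactive gap relative to the
#'   wild type, kcal/mol (0 for the wild type; may be `NA` for variants that
#'   are only used in closed-form indicator comparisons).
#' @param atp_site_mutant logical; `TRUE` when the mutated residue forms or
#'   borders the ATP site (T315I, T315M and compounds containing them).
#' @return an object of class `enzyme_variant`.
#' @examples
#' wt <- enzyme_variant("Wild-type", kcat = 66, KM = 17,
#'                      ic50 = c(imatinib = 527, ponatinib = 2.1, dasatinib = 1.8))
#' @export
enzyme_variant <- function(name, kcat, KM, ic50, ddG = 0, atp_site_mutant = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(kcat) || length(kcat) != 1L || kcat <= 0)
    stop("kcat must be a single positive number (min^-1)")
  if (!is.numeric(KM) || length(KM) != 1L || KM <= 0)
    stop("KM must be a single positive number (uM)")
  if (length(ic50) && (is.null(names(ic50)) || any(!nzchar(names(ic50)))))
    stop("ic50 must be a named vector (names are drug identifiers)")
  if (any(ic50 <= 0, na.rm = TRUE)) stop("every IC50 must be > 0")
  structure(list(name = name, kcat = kcat, KM = KM,
                 ic50 = ic50, ddG = ddG,
                 atp_site_mutant = isTRUE(atp_site_mutant)),
            class = "enzyme_variant")
}

#' @export
print.enzyme_variant <- function(x, ...) {
  cat("<enzyme_variant> ", x$name, "\n", sep = "")
  cat("  kcat ", x$kcat, " min^-1,  KM ", x$KM, " uM,  ddG ",
      x$ddG, " kcal/mol", if (x$atp_site_mutant) "  [ATP-site residue]", "\n",
      sep = "")
  if (length(x$ic50))
    cat("  IC50 (nM): ",
        paste(names(x$ic50), signif(x$ic50, 4), sep = " = ", collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Define an inhibitor drug
#'
#' @param name drug identifier.
#' @param binding_mode `"inactive_binder"` (binds only the inactive enzyme
#'   conformation; imatinib, ponatinib) or `"active_binder"` (binds only the
#'   active conformation; dasatinib).
#' @param tR residence time of the drug on the wild-type enzyme, min.
#' @param koffR wild-type unbinding rate constant, min^-1.  Defaults to
#'   `1/tR`; a different value may be supplied when a published off-rate
#'   takes precedence over the published residence time.
#' @param pk optional [pk_inputs()] object with the raw pharmacokinetic
#'   parameters of the drug.
#' @param pk_printed optional [pk_constants()] object carrying published
#'   concentration-curve constants.
#' @return an object of class `drug_spec`.
#' @export
drug_spec <- function(name, binding_mode = c("inactive_binder", "active_binder"),
                      tR, koffR = NULL, pk = NULL, pk_printed = NULL) {
  binding_mode <- match.arg(binding_mode)
  if (!is.numeric(tR) || length(tR) != 1L || tR <= 0)
    stop("tR must be a single positive residence time in minutes")
  if (is.null(koffR)) koffR <- residence_to_koff(tR)
  if (koffR <= 0) stop("koffR must be > 0")
  structure(list(name = name, binding_mode = binding_mode, tR = tR,
                 koffR = koffR, pk = pk, pk_printed = pk_printed),
            class = "drug_spec")
}

#' @export
print.drug_spec <- function(x, ...) {
  cat("<drug_spec> ", x$name, " (", x$binding_mode, ")\n", sep = "")
  cat("  residence time ", x$tR, " min, koffR ", signif(x$koffR, 3),
      " min^-1\n", sep = "")
  invisible(x)
}

#' Thermodynamic and system-composition settings
#'
#' Controls how the active/inactive free-energy difference enters the model
#' and fixes the substrate and total-enzyme concentrations.  Under the
#' default `"effective_unity"` convention the Boltzmann factor of the
#' active-inactive gap is taken as exactly 1 for every variant; this is the
#' effective parameterisation under which the published dissociation-constant
#' tables are internally consistent (the wild-type gap of about -1 kcal/mol
#' is treated as giving a factor of order one, and mutant shifts are small).
#' The `"per_mole_RT"` convention evaluates `exp(-(dG_WT + ddG) / (R T))`
#' with the molar gas constant in kcal/(mol K) and is intended for
#' sensitivity analysis.
#'
#' @param dG_WT wild-type inactive-to-active free-energy difference,
#'   kcal/mol (negative when the active state is favoured).
#' @param convention `"effective_unity"` or `"per_mole_RT"`.
#' @param temperature Kelvin.
#' @param S substrate concentration, uM (held constant by the model).
#' @param Etot total enzyme concentration, uM.
#' @return an object of class `thermo_config`.
#' @export
thermo_config <- function(dG_WT = -1,
                          convention = c("effective_unity", "per_mole_RT"),
                          temperature = 300, S = 10, Etot = 1) {
  convention <- match.arg(convention)
  stopifnot(temperature > 0, S >= 0, Etot > 0)
  structure(list(dG_WT = dG_WT, convention = convention,
                 temperature = temperature, S = S, Etot = Etot),
            class = "thermo_config")
}

#' @export
print.thermo_config <- function(x, ...) {
  cat("<thermo_config> convention ", x$convention,
      ", dG_WT ", x$dG_WT, " kcal/mol, T ", x$temperature, " K\n",
      "  [S] ", x$S, " uM, [Etot] ", x$Etot, " uM\n", sep = "")
  invisible(x)
}
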