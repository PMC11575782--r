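# Resistance indicators: the simulation-based inhibitory reduction
# prowess (IRP) and the closed-form quantities it is compared against.

#' Inhibitory reduction prowess (IRP)
#'
#' The percentage by which treatment reduces the product formation rate,
#' evaluated at the steady-state inter-dose midpoint:
#' `IRP = 100 (rate(0) - rate(t_mid)) / rate(0)`, with `t_mid` half a day
#' after the day-10 dose (9.5 days since the first dose).  The reported
#' range comes from the minimum and maximum product rates over the day-10
#' window.
#'
#' @param traj an `enzyme_trajectory` spanning at least `window[2]` minutes.
#' @param baseline untreated product formation rate, uM min^-1 (default:
#'   the closed-form zero-inhibitor rate, which equals the simulated t = 0
#'   rate by the fixed-point property of the initial state).
#' @param mid_time evaluation time of the midpoint IRP, minutes.
#' @param window day window for the range, minutes (half-open).
#' @return named vector `c(mid =, min =, max =)` in percent; `min`/`max`
#'   bound the IRP over the window (so `min` comes from the largest rate).
#' @export
irp <- function(traj, baseline = NULL, mid_time = 9.5 * 1440,
                window = c(9 * 1440, 10 * 1440)) {
  stopifnot(inherits(traj, "enzyme_trajectory"))
  if (max(traj$times) < window[2] - 1e-9 || max(traj$times) < mid_time)
    stop("trajectory too short: IRP needs coverage up to ",
         window[2] / 1440, " days")
  if (is.null(baseline)) baseline <- analytic_product_rate(traj$params, 0)
  stopifnot(baseline > 0)
  rate <- traj$product_rate
  mid_rate <- stats::approx(traj$times, rate, xout = mid_time)$y
  sel <- traj$times >= window[1] & traj$times < window[2]
  c(mid = 100 * (baseline - mid_rate) / baseline,
    min = 100 * (baseline - max(rate[sel])) / baseline,
    max = 100 * (baseline - min(rate[sel])) / baseline)
}

#' Effective IC50 ratio
#'
#' `IC50 / (IC50 + R)`: the fraction of the untreated product formation
#' rate that survives at inhibitor concentration `R`.  Values above 0.5
#' (inhibitor below the IC50) mark a state of resistance.
#'
#' @param ic50 IC50, nM.
#' @param R inhibitor concentration, nM (vectorised).
#' @return dimensionless ratio in (0, 1].
#' @export
effective_ic50_ratio <- function(ic50, R) {
  if (any(ic50 <= 0)) stop("ic50 must be > 0")
  if (any(R < 0)) stop("R must be >= 0")
  ic50 / (ic50 + R)
}

#' Relative (fold) IC50 of a mutant versus the wild type
#'
#' @param ic50_mut,ic50_wt IC50 values, nM.
#' @return dimensionless ratio.
#' @export
relative_ic50 <- function(ic50_mut, ic50_wt) {
  if (any(ic50_mut <= 0) || any(ic50_wt <= 0)) stop("IC50 values must be > 0")
  ic50_mut / ic50_wt
}

#' Catalytic efficiency
#'
#' @param kcat turnover number, min^-1.
#' @param KM Michaelis constant, uM.
#' @return `kcat / KM`, uM^-1 min^-1.
#' @export
catalytic_efficiency <- function(kcat, KM) {
  if (any(kcat <= 0) || any(KM <= 0)) stop("kcat and KM must be > 0")
  kcat / KM
}

#' Substrate saturation fraction
#'
#' @param S substrate concentration, uM.
#' @param KM Michaelis constant, uM.
#' @return `S / (S + KM)` in `[0, 1)`.
#' @export
saturation_fraction <- function(S, KM) {
  if (any(S < 0)) stop("S must be >= 0")
  if (any(KM <= 0)) stop("KM must be > 0")
  S / (S + KM)
}

#' Effective IC50 ratio over one steady-state day
#'
#' Samples the plasma concentration at `grid_step`-minute resolution over
#' the requested day and converts it pointwise to the effective IC50 ratio.
#'
#' @param ic50 IC50, nM.
#' @param constants a `pk_constants` object.
#' @param day 1-based day index (default 10, the steady-state day).
#' @param grid_step sampling step, minutes.
#' @return data.frame with `time_min` and `ratio`.
#' @export
effective_ratio_day <- function(ic50, constants, day = 10, grid_step = 1) {
  tau_min <- constants$tau * 60
  times <- seq((day - 1) * tau_min, day * tau_min - grid_step, by = grid_step)
  R <- plasma_concentration(times, constants)
  data.frame(time_min = times, ratio = effective_ic50_ratio(ic50, R))
}

#' Indicator report for variant x drug combinations
#'
#' Runs the full pipeline (parameter derivation, multi-dose concentration
#' curve, four-state simulation) for each requested combination and
#' collects the IRP (midpoint and day-10 range), the effective IC50 ratio
#' (at the midpoint and its day-10 range), the relative IC50, catalytic
#' efficiency, saturation fraction, maximal velocity and the resistance
#' annotation.
#'
#' @param bundle a [load_fixtures()] bundle.
#' @param variants character vector of variant names (default: the
#'   simulated set).
#' @param drugs character vector of drug names (default: all three).
#' @param thermo a [thermo_config()].
#' @param pk_mode `"printed"` (use published curve constants) or
#'   `"derived"` (recompute them from the raw inputs).
#' @param config a [sim_config()] covering at least 10 days.
#' @return data.frame of class `indicator_report`, one row per combination.
#' @export
comparison_report <- function(bundle, variants = NULL, drugs = NULL,
                              thermo = thermo_config(),
                              pk_mode = c("printed", "derived"),
                              config = sim_config()) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  pk_mode <- match.arg(pk_mode)
  if (is.null(variants)) variants <- simulated_variant_names(bundle)
  if (length(drugs) == 0 && !is.null(drugs)) stop("empty drug list")
  all_drugs <- bundle_drugs(bundle)
  if (is.null(drugs)) drugs <- vapply(all_drugs, `[[`, "", "name")
  if (!length(drugs)) stop("empty drug list")
  wt_var <- bundle_variant(bundle, "Wild-type")
  rows <- list()
  for (dn in drugs) {
    d <- all_drugs[[dn]]
    if (is.null(d)) stop("unknown drug '", dn, "'")
    cst <- drug_pk_constants(bundle, dn, mode = pk_mode)
    wt_params <- build_parameter_set(wt_var, d, thermo)
    for (vn in variants) {
      v <- bundle_variant(bundle, vn)
      p <- if (vn == "Wild-type") wt_params else
        build_parameter_set(v, d, thermo, wt_params)
      traj <- simulate_enzyme(p, cst, config)
      irp_v <- irp(traj)
      eff <- effective_ratio_day(p$ic50, cst)
      mid_t <- 9.5 * 1440
      eff_mid <- eff$ratio[which.min(abs(eff$time_min - mid_t))]
      rows[[length(rows) + 1L]] <- data.frame(
        variant = vn, drug = dn,
        irp_mid = unname(irp_v["mid"]),
        irp_min = unname(irp_v["min"]),
        irp_max = unname(irp_v["max"]),
        eff_ratio_mid = eff_mid,
        eff_ratio_min = min(eff$ratio),
        eff_ratio_max = max(eff$ratio),
        relative_ic50 = relative_ic50(p$ic50, wt_params$ic50),
        catalytic_efficiency = catalytic_efficiency(v$kcat, v$KM),
        saturation = saturation_fraction(thermo$S, v$KM),
        vmax = v$kcat * thermo$Etot,
        annotation = bundle_annotation(bundle, vn, dn),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("indicator_report", class(out))
  out
}
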