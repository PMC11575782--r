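# Multiple-dose one-compartment pharmacokinetics with first-order
# absorption and elimination.  External time unit is minutes since the
# first dose; the rate constants ka/ke are per hour as published.

#' Raw pharmacokinetic inputs for one drug
#'
#' @param F_bio bioavailable fraction, in (0, 1].
#' @param D_mass dose per intake, mg.
#' @param M molar mass, g/mol.
#' @param ka first-order absorption rate constant, h^-1.
#' @param t_half_e elimination half-life, h.
#' @param Vd volume of distribution, L.
#' @param tau dosing interval, h.
#' @return an object of class `pk_inputs`; the elimination rate constant
#'   `ke = ln 2 / t_half_e` is stored alongside.
#' @export
pk_inputs <- function(F_bio = 1, D_mass, M, ka, t_half_e, Vd, tau = 24) {
  stopifnot(F_bio > 0, F_bio <= 1, D_mass > 0, M > 0, ka > 0,
            t_half_e > 0, Vd > 0, tau > 0)
  structure(list(F_bio = F_bio, D_mass = D_mass, M = M, ka = ka,
                 t_half_e = t_half_e, ke = log(2) / t_half_e,
                 Vd = Vd, tau = tau),
            class = "pk_inputs")
}

#' Derive the concentration-curve constants from raw inputs
#'
#' The multi-dose plasma-concentration solution is written with three
#' constants: the concentration scale
#' `Gamma = F D ka / (Vd (ka - ke))` (dose in moles, expressed here in nM),
#' and the per-interval accumulation factors `alpha = exp(ka tau)` and
#' `epsilon = exp(ke tau)`.
#'
#' @param inputs a [pk_inputs()] object.
#' @return an object of class `pk_constants` with `source = "derived"`.
#' @examples
#' pon <- pk_inputs(D_mass = 45, M = 532.6, ka = 1.302, t_half_e = 24, Vd = 1223)
#' pk_constants(pon)$Gamma   # 70.65 nM
#' @export
pk_constants <- function(inputs) {
  stopifnot(inherits(inputs, "pk_inputs"))
  ka <- inputs$ka; ke <- inputs$ke
  if (abs(ka - ke) < 1e-12 * max(ka, ke))
    stop("ka = ke: the two-exponential solution Gamma/(ka - ke) is singular; ",
         "use distinct absorption and elimination rate constants")
  D_umol <- inputs$D_mass * 1000 / inputs$M
  Gamma_nM <- 1000 * inputs$F_bio * D_umol * ka / (inputs$Vd * (ka - ke))
  new_pk_constants(Gamma = Gamma_nM,
                   log_alpha = ka * inputs$tau, log_eps = ke * inputs$tau,
                   ka = ka, ke = ke, tau = inputs$tau, source = "derived")
}

#' Concentration-curve constants taken verbatim from a publication
#'
#' @param Gamma concentration scale, nM.
#' @param alpha absorption accumulation factor per dosing interval.
#' @param epsilon elimination accumulation factor per dosing interval.
#' @param ka,ke absorption and elimination rate constants, h^-1.
#' @param tau dosing interval, h.
#' @return an object of class `pk_constants` with `source = "printed"`.
#' @export
pk_constants_printed <- function(Gamma, alpha, epsilon, ka, ke, tau = 24) {
  new_pk_constants(Gamma = Gamma, log_alpha = log(alpha),
                   log_eps = log(epsilon), ka = ka, ke = ke, tau = tau,
                   source = "printed")
}

new_pk_constants <- function(Gamma, log_alpha, log_eps, ka, ke, tau, source) {
  stopifnot(Gamma > 0, log_alpha > log_eps, log_eps > 0)
  structure(list(Gamma = Gamma, alpha = exp(log_alpha), epsilon = exp(log_eps),
                 log_alpha = log_alpha, log_eps = log_eps,
                 ka = ka, ke = ke, tau = tau, source = source),
            class = "pk_constants")
}

#' @export
print.pk_constants <- function(x, ...) {
  cat("<pk_constants> (", x$source, ")\n", sep = "")
  cat(sprintf("  Gamma %.4g nM, alpha %.3g, epsilon %.4g; ka %.4g h^-1, ke %.4g h^-1, tau %g h\n",
              x$Gamma, x$alpha, x$epsilon, x$ka, x$ke, x$tau))
  invisible(x)
}

#' Plasma concentration under regular daily dosing
#'
#' Evaluates the multi-dose solution
#' `C(t) = Gamma (e^{-ke t} sum_j epsilon^j - e^{-ka t} sum_j alpha^j)`
#' with `j = 0..n`, `n = floor(t/tau)` complete dosing intervals elapsed
#' (the dose at `t = n tau` counts from that instant).  The sums are
#' evaluated per dose as `exp(-k t + j log(alpha))`, which is algebraically
#' identical but never materialises `alpha^j` (which overflows double
#' precision within a few simulated days for fast absorbers).
#'
#' @param t_min time since the first dose, minutes (vectorised).
#' @param constants a `pk_constants` object.
#' @return plasma concentration, nM.
#' @export
plasma_concentration <- function(t_min, constants) {
  stopifnot(inherits(constants, "pk_constants"))
  if (any(t_min < 0)) stop("t_min must be >= 0")
  th <- t_min / 60
  n <- floor(th / constants$tau)
  jmax <- max(n)
  j <- 0:jmax
  # one column per dose; masked beyond the doses actually taken
  decay <- exp(outer(-constants$ke * th, j * constants$log_eps, `+`))
  absorb <- exp(outer(-constants$ka * th, j * constants$log_alpha, `+`))
  taken <- outer(n, j, `>=`)
  vals <- constants$Gamma *
    (rowSums(decay * taken) - rowSums(absorb * taken))
  as.numeric(vals)
}

#' Dosing schedule
#'
#' @param n_days number of daily doses.
#' @param jitter_width half-width of the uniform perturbation of each dose
#'   time, h (0 = perfectly regular).  Doses after the first are drawn at
#'   `k tau + U(-jitter_width, +jitter_width)`; the first dose stays at
#'   t = 0 so the concentration at time zero is exactly zero.
#' @param seed integer seed making the jitter reproducible.
#' @return an object of class `dose_schedule`.
#' @export
dose_schedule <- function(n_days, jitter_width = 0, seed = 1L) {
  stopifnot(n_days >= 1, jitter_width >= 0)
  structure(list(n_days = as.integer(n_days), jitter_width = jitter_width,
                 seed = as.integer(seed)),
            class = "dose_schedule")
}

dose_times_h <- function(schedule, tau) {
  if (schedule$jitter_width >= tau / 2)
    stop("jitter_width must be below half the dosing interval")
  k <- seq_len(schedule$n_days) - 1L
  times <- k * tau
  if (schedule$jitter_width > 0 && schedule$n_days > 1L) {
    jit <- local_seed_runif(schedule$seed, schedule$n_days - 1L,
                            -schedule$jitter_width, schedule$jitter_width)
    times[-1L] <- times[-1L] + jit
  }
  times
}

# uniform draws under a temporary RNG state
local_seed_runif <- function(seed, n, lo, hi) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::runif(n, lo, hi)
}

#' Concentration time series for a dosing schedule
#'
#' For a regular schedule this evaluates the closed-form multi-dose
#' solution; for a jittered schedule it sums the per-dose contributions
#' `Gamma a_j (e^{-ke (t - t_j)} - (b_j/a_j) e^{-ka (t - t_j)})` explicitly
#' over the doses taken before `t` (with per-dose amplitudes `a_j`, `b_j`
#' equal to 1 when the curve constants are self-consistent, so that zero
#' jitter reproduces the closed form to machine precision in either
#' constants mode).
#'
#' @param schedule a [dose_schedule()].
#' @param constants a `pk_constants` object.
#' @param grid_step output grid step, minutes.
#' @return an object of class `concentration_series` with `times` (min),
#'   `values` (nM) and the realised `dose_times` (min).
#' @export
concentration_series <- function(schedule, constants, grid_step = 1) {
  stopifnot(inherits(schedule, "dose_schedule"),
            inherits(constants, "pk_constants"), grid_step > 0)
  horizon <- schedule$n_days * constants$tau * 60
  times <- seq(0, horizon, by = grid_step)
  d_h <- dose_times_h(schedule, constants$tau)
  j <- seq_along(d_h) - 1L
  # amplitudes reconciling printed accumulation factors with the per-dose form
  a <- exp(j * constants$log_eps - constants$ke * j * constants$tau)
  b <- exp(j * constants$log_alpha - constants$ka * j * constants$tau)
  th <- times / 60
  dt <- outer(th, d_h, `-`)          # hours since each dose
  active <- dt >= 0
  dt[!active] <- 0
  vals <- constants$Gamma * rowSums(
    (sweep(exp(-constants$ke * dt), 2, a, `*`) -
     sweep(exp(-constants$ka * dt), 2, b, `*`)) * active)
  structure(list(times = times, values = as.numeric(vals),
                 dose_times = d_h * 60, constants = constants,
                 schedule = schedule),
            class = "concentration_series")
}

#' @export
print.concentration_series <- function(x, ...) {
  cat("<concentration_series> ", length(x$times), " samples over ",
      max(x$times) / 1440, " days; ", length(x$dose_times), " doses",
      if (x$schedule$jitter_width > 0)
        paste0(" (jitter +-", x$schedule$jitter_width, " h, seed ",
               x$schedule$seed, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Daily minimum, maximum and inter-dose midpoint of a concentration series
#'
#' @param series a [concentration_series()].
#' @param day 1-based day index; day `d` covers `[(d-1) tau, d tau)`.
#' @return named vector `c(min =, max =, midpoint =)` in nM; the midpoint
#'   is the value half a dosing interval after that day's dose.
#' @export
steady_state_summary <- function(series, day) {
  stopifnot(inherits(series, "concentration_series"))
  tau_min <- series$constants$tau * 60
  lo <- (day - 1) * tau_min
  hi <- day * tau_min
  if (lo < 0 || hi > max(series$times) + 1e-9)
    stop("day ", day, " is outside the simulated series")
  sel <- series$times >= lo & series$times < hi
  if (!any(sel)) stop("no samples in day ", day)
  mid_t <- lo + tau_min / 2
  mid <- stats::approx(series$times, series$values, xout = mid_t)$y
  c(min = min(series$values[sel]), max = max(series$values[sel]),
    midpoint = mid)
}
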