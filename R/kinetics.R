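# Four-state enzyme kinetics under a time-varying inhibitor concentration.
# States: free inactive (E_I), free active (E_A), substrate-bound active
# (E_AS), and inhibitor-bound (E_IR for inactive-state binders, E_AR for
# active-state binders).  The system is linear and non-autonomous; the
# inhibitor concentration enters through the binding column only.

#' State labels for a binding mode
#'
#' @param binding_mode `"inactive_binder"` or `"active_binder"`.
#' @return character vector of the four state labels.
#' @export
state_labels <- function(binding_mode = c("inactive_binder", "active_binder")) {
  binding_mode <- match.arg(binding_mode)
  c("E_I", "E_A", "E_AS",
    if (binding_mode == "inactive_binder") "E_IR" else "E_AR")
}

#' Integration settings
#'
#' @param method `"adaptive"` (variable-step solver, default) or
#'   `"euler_fixed"` (explicit Euler at a fixed step, the bit-reproducible
#'   reference).
#' @param dt fixed Euler step, minutes (default 1 ms).
#' @param duration simulated time, minutes.
#' @param out_step spacing of stored samples, minutes.
#' @param rel_tol,abs_tol tolerances for the adaptive solver.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(method = c("adaptive", "euler_fixed"),
                       dt = 1 / 60000, duration = 14400, out_step = 1,
                       rel_tol = 1e-8, abs_tol = 1e-12) {
  method <- match.arg(method)
  stopifnot(dt > 0, duration > 0, out_step > 0)
  structure(list(method = method, dt = dt, duration = duration,
                 out_step = out_step, rel_tol = rel_tol, abs_tol = abs_tol),
            class = "sim_config")
}

#' Transition-rate generator matrix at a given inhibitor concentration
#'
#' Returns the 4 x 4 matrix `M` such that `d y / dt = M y`, with columns
#' indexed by the source state; every column sums to zero, so total enzyme
#' is conserved exactly.  Catalysis returns substrate-bound enzyme to the
#' free active state at `kcat` (substrate is replenished and not a dynamic
#' species), on top of unbinding at `koffS`.
#'
#' @param params a [build_parameter_set()] result.
#' @param R inhibitor concentration, nM.
#' @return 4 x 4 numeric matrix with dimnames from [state_labels()].
#' @export
rate_matrix <- function(params, R) {
  stopifnot(inherits(params, "variant_drug_parameters"))
  if (R < 0) stop("inhibitor concentration must be >= 0")
  parts <- rate_matrix_parts(params)
  M <- parts$M0 + R * parts$M1
  dimnames(M) <- list(parts$labels, parts$labels)
  M
}

# split M(R) = M0 + R * M1 (binding terms are linear in R)
rate_matrix_parts <- function(params) {
  labels <- state_labels(params$drug$binding_mode)
  konS_S <- params$substrate$konS * params$thermo$S
  ret <- params$substrate$koffS + params$variant$kcat
  M0 <- matrix(0, 4, 4)
  M1 <- matrix(0, 4, 4)
  # conformational switch E_I <-> E_A
  M0[2, 1] <- params$ktransI
  M0[1, 2] <- params$ktransA
  # substrate binding E_A <-> E_AS (return includes catalysis)
  M0[3, 2] <- konS_S
  M0[2, 3] <- ret
  # inhibitor binding on E_I or E_A per binding mode
  src <- if (params$drug$binding_mode == "inactive_binder") 1L else 2L
  M1[4, src] <- params$inhibitor$konR
  M0[src, 4] <- params$inhibitor$koffR
  diag(M0) <- diag(M0) - colSums(M0)
  diag(M1) <- diag(M1) - colSums(M1)
  list(M0 = M0, M1 = M1, labels = labels)
}

#' Quasi-equilibrium state of the untreated system
#'
#' The no-inhibitor steady state follows from the state weights
#' `(1, f, f S/KM, 0)` normalised by `W0 = f (1 + S/KM) + 1` and scaled by
#' the total enzyme concentration; it is the exact fixed point of the
#' generator at zero inhibitor and is used as the initial condition for
#' treatment simulations.
#'
#' @param params a [build_parameter_set()] result.
#' @param Etot total enzyme concentration, uM (default from the thermo
#'   configuration).
#' @return named state vector, uM.
#' @export
equilibrium_state <- function(params, Etot = params$thermo$Etot) {
  f <- params$factor
  sk <- params$thermo$S / params$variant$KM
  W0 <- f * (1 + sk) + 1
  y <- Etot * c(1, f, f * sk, 0) / W0
  names(y) <- state_labels(params$drug$binding_mode)
  y
}

#' Closed-form quasi-equilibrium product formation rate
#'
#' At a constant inhibitor concentration the product formation rate is
#' `kcat Etot f (S/KM) / Wtot`, where the total state weight `Wtot` is
#' `f (1 + S/KM) + 1 + R/RD` for an inactive-state binder and
#' `f (1 + S/KM + R/RD) + 1` for an active-state binder.  With the
#' dissociation constant derived from the IC50 this is identical to
#' `rate(0) * IC50 / (IC50 + R)`.
#'
#' @param params a [build_parameter_set()] result.
#' @param R inhibitor concentration, nM (vectorised).
#' @param Etot total enzyme concentration, uM.
#' @return product formation rate, uM min^-1.
#' @export
analytic_product_rate <- function(params, R, Etot = params$thermo$Etot) {
  if (any(R < 0)) stop("inhibitor concentration must be >= 0")
  f <- params$factor
  sk <- params$thermo$S / params$variant$KM
  RD <- params$inhibitor$RD
  Wtot <- if (params$drug$binding_mode == "inactive_binder")
    f * (1 + sk) + 1 + R / RD
  else
    f * (1 + sk + R / RD) + 1
  params$variant$kcat * Etot * f * sk / Wtot
}

#' Simulate the four-state system under a fluctuating inhibitor
#'
#' Advances the linear non-autonomous rate equations with the inhibitor
#' concentration taken from `conc`, which may be a single number (constant
#' concentration), a `pk_constants` object (regular daily dosing evaluated
#' in closed form), a [concentration_series()] (interpolated; this is how
#' jittered schedules are simulated), or a function of time in minutes
#' returning nM.  The default integrator is a variable-step solver
#' ([deSolve::lsoda()]); `method = "euler_fixed"` runs the explicit Euler
#' reference at a 1 ms step in compiled code (constant or `pk_constants`
#' concentrations only).
#'
#' @param params a [build_parameter_set()] result.
#' @param conc inhibitor concentration input, see Details.
#' @param config a [sim_config()].
#' @param init initial state vector, uM (default [equilibrium_state()]).
#' @return an object of class `enzyme_trajectory`: `times` (min), `states`
#'   (matrix, uM), `inhibitor` (nM), `product_rate` (uM min^-1), `params`.
#' @export
simulate_enzyme <- function(params, conc, config = sim_config(),
                            init = equilibrium_state(params)) {
  stopifnot(inherits(params, "variant_drug_parameters"),
            inherits(config, "sim_config"))
  labels <- state_labels(params$drug$binding_mode)
  stopifnot(length(init) == 4L, all(init >= 0))
  parts <- rate_matrix_parts(params)
  times <- seq(0, config$duration, by = config$out_step)
  if (times[length(times)] < config$duration)
    times <- c(times, config$duration)

  if (config$method == "euler_fixed") {
    nsteps <- round(config$duration / config$dt)
    stride <- max(1L, round(config$out_step / config$dt))
    if (inherits(conc, "pk_constants")) {
      out <- euler_schedule_cpp(init, parts$M0, parts$M1, config$dt, nsteps,
                                stride, conc$Gamma, conc$log_alpha,
                                conc$log_eps, conc$ka, conc$ke, conc$tau)
    } else if (is.numeric(conc) && length(conc) == 1L) {
      out <- euler_constant_cpp(init, parts$M0, parts$M1, conc,
                                config$dt, nsteps, stride)
    } else {
      stop("euler_fixed supports a constant concentration or pk_constants")
    }
    times <- out$times
    states <- out$states
    inhibitor <- out$inhibitor
  } else {
    conc_fn <- as_conc_fn(conc)
    rhs <- function(t, y, p) {
      R <- conc_fn(t)
      list(as.numeric(parts$M0 %*% y + R * (parts$M1 %*% y)))
    }
    sol <- deSolve::lsoda(y = unname(init), times = times, func = rhs,
                          parms = NULL, rtol = config$rel_tol,
                          atol = config$abs_tol)
    states <- unname(sol[, 2:5, drop = FALSE])
    inhibitor <- vapply(times, conc_fn, numeric(1))
  }
  if (min(states) < -1e-12)
    stop("integration produced a negative state concentration (",
         format(min(states), digits = 3),
         "); reduce the step size or tolerances")
  colnames(states) <- labels
  structure(list(times = times, states = states, inhibitor = inhibitor,
                 product_rate = params$variant$kcat * states[, "E_AS"],
                 params = params),
            class = "enzyme_trajectory")
}

as_conc_fn <- function(conc) {
  if (inherits(conc, "pk_constants")) {
    cst <- conc
    function(t) plasma_concentration(t, cst)
  } else if (inherits(conc, "concentration_series")) {
    fn <- stats::approxfun(conc$times, conc$values, rule = 2)
    function(t) fn(t)
  } else if (is.function(conc)) {
    conc
  } else if (is.numeric(conc) && length(conc) == 1L) {
    function(t) conc
  } else {
    stop("conc must be a number, a function(t), pk_constants, or a ",
         "concentration_series")
  }
}

#' @export
print.enzyme_trajectory <- function(x, ...) {
  cat("<enzyme_trajectory> ", x$params$variant$name, " x ",
      x$params$drug$name, ": ", length(x$times), " samples over ",
      round(max(x$times) / 1440, 3), " days\n", sep = "")
  cat(sprintf("  final product rate %.4g uM/min; enzyme total %.6g uM\n",
              x$product_rate[length(x$product_rate)],
              sum(x$states[nrow(x$states), ])))
  invisible(x)
}

#' Product formation rate along a trajectory
#'
#' @param traj an `enzyme_trajectory`.
#' @return numeric vector, `kcat * [E_AS](t)` in uM min^-1.
#' @export
product_rate_series <- function(traj) {
  stopifnot(inherits(traj, "enzyme_trajectory"))
  traj$product_rate
}

#' Relaxation time of the four-state system at constant inhibitor
#'
#' The slowest non-zero decay rate of the generator spectrum; useful for
#' choosing how long a constant-concentration simulation must run to reach
#' quasi-equilibrium to a given accuracy.
#'
#' @param params a [build_parameter_set()] result.
#' @param R inhibitor concentration, nM.
#' @return slowest relaxation time, minutes.
#' @export
relaxation_time <- function(params, R) {
  M <- rate_matrix(params, R)
  ev <- Re(eigen(M, only.values = TRUE)$values)
  decay <- -ev[ev < -1e-12]
  1 / min(decay)
}
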