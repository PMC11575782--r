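test_that("generator columns sum to zero and binding scales with concentration", {
  for (combo in list(c("Wild-type", "imatinib"), c("T315M", "dasatinib"),
                     c("G250E", "ponatinib"))) {
    p <- params_for(combo[1], combo[2])
    for (R in c(0, 50, 2000)) {
      M <- rate_matrix(p, R)
      expect_equal(colSums(M), rep(0, 4), tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
    # no inhibitor: the bound state only drains
    M0 <- rate_matrix(p, 0)
    bound <- state_labels(p$drug$binding_mode)[4]
    expect_identical(unname(M0[bound, setdiff(rownames(M0), bound)]),
                     rep(0, 3))
    expect_true(M0[bound, bound] < 0 || p$inhibitor$koffR == 0)
  }
  expect_error(rate_matrix(params_for("Wild-type", "imatinib"), -1), ">= 0")
})

test_that("binding flux balances unbinding at the dissociation constant", {
  p <- wt_params_for("imatinib")
  M <- rate_matrix(p, p$inhibitor$RD)
  expect_equal(M["E_IR", "E_I"], p$inhibitor$koffR, tolerance = 1e-12)
})

test_that("state space depends on the binding mode", {
  expect_identical(state_labels("inactive_binder"),
                   c("E_I", "E_A", "E_AS", "E_IR"))
  expect_identical(state_labels("active_binder"),
                   c("E_I", "E_A", "E_AS", "E_AR"))
})

test_that("untreated equilibrium state has the analytic composition", {
  p <- wt_params_for("imatinib")
  y <- equilibrium_state(p)
  expect_equal(unname(y), c(0.3864, 0.3864, 0.2272, 0), tolerance = 1e-3)
  expect_equal(sum(y), 1)
  # no substrate: bound-substrate state empty, free states split by the factor
  p0 <- build_parameter_set(bundle_variant(.bundle, "Wild-type"),
                            .drugs$imatinib, thermo_config(S = 0))
  y0 <- equilibrium_state(p0)
  expect_equal(unname(y0), c(0.5, 0.5, 0, 0))
  # normalisation holds for non-unit thermodynamic factors
  pm <- build_parameter_set(bundle_variant(.bundle, "Wild-type"),
                            .drugs$imatinib,
                            thermo_config(convention = "per_mole_RT"))
  expect_equal(sum(equilibrium_state(pm)), 1)
})

test_that("the untreated equilibrium is a numerical fixed point", {
  p <- params_for("E255K", "imatinib")
  traj <- simulate_enzyme(p, 0, sim_config(duration = 1440, out_step = 60))
  drift <- apply(traj$states, 2, function(col) max(abs(col - col[1])))
  expect_true(max(drift) < 1e-8)
  expect_equal(product_rate_series(traj),
               rep(analytic_product_rate(p, 0), length(traj$times)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("closed-form rate halves at the IC50 and follows the hyperbola", {
  for (combo in list(c("Wild-type", "imatinib"), c("E255K", "dasatinib"))) {
    p <- params_for(combo[1], combo[2])
    r0 <- analytic_product_rate(p, 0)
    expect_equal(analytic_product_rate(p, p$ic50), r0 / 2)
    R <- c(0.1, 1, 50, 1e3, 1e5)
    expect_equal(analytic_product_rate(p, R),
                 r0 * p$ic50 / (p$ic50 + R), tolerance = 1e-12)
  }
  # wild-type untreated rate: kcat * [E_AS] at quasi-equilibrium
  expect_equal(analytic_product_rate(wt_params_for("imatinib"), 0),
               15.0, tolerance = 1e-3)
})

test_that("simulation at constant inhibitor reaches the quasi-equilibrium composition", {
  for (combo in list(c("E255K", "imatinib"), c("T315I", "dasatinib"))) {
    p <- params_for(combo[1], combo[2])
    R <- p$ic50
    horizon <- 40 * relaxation_time(p, R)
    traj <- simulate_enzyme(p, R, sim_config(duration = horizon,
                                             out_step = horizon,
                                             rel_tol = 1e-10))
    final <- traj$states[nrow(traj$states), ]
    f <- p$factor; sk <- p$thermo$S / p$variant$KM
    wbound <- if (p$drug$binding_mode == "inactive_binder")
      R / p$inhibitor$RD else f * R / p$inhibitor$RD
    w <- c(1, f, f * sk, wbound)
    expect_equal(unname(final), p$thermo$Etot * w / sum(w), tolerance = 1e-6)
    # product rate halves at R = IC50
    rate <- p$variant$kcat * final[["E_AS"]]
    expect_equal(rate / analytic_product_rate(p, 0), 0.5, tolerance = 2e-3)
  }
})

test_that("fixed-step Euler reference and adaptive solver agree over one day", {
  p <- params_for("E255K", "imatinib")
  cst <- drug_pk_constants(.bundle, "imatinib")
  cfg_e <- sim_config("euler_fixed", duration = 1440)
  cfg_a <- sim_config("adaptive", duration = 1440)
  te <- simulate_enzyme(p, cst, cfg_e)
  ta <- simulate_enzyme(p, cst, cfg_a)
  expect_equal(te$times, ta$times)
  rel <- abs(te$product_rate - ta$product_rate) / ta$product_rate
  expect_true(max(rel) < 1e-3)
  # enzyme conservation along both trajectories
  expect_true(max(abs(rowSums(te$states) - 1)) < 1e-6)
  expect_true(max(abs(rowSums(ta$states) - 1)) < 1e-6)
})

test_that("euler integrator rejects concentration inputs it cannot evaluate", {
  p <- wt_params_for("imatinib")
  expect_error(simulate_enzyme(p, function(t) 100,
                               sim_config("euler_fixed", duration = 1)),
               "constant concentration or pk_constants")
})

test_that("trajectories can be driven by an interpolated concentration series", {
  p <- wt_params_for("ponatinib")
  cst <- drug_pk_constants(.bundle, "ponatinib")
  ser <- concentration_series(dose_schedule(2), cst)
  t_ser <- simulate_enzyme(p, ser, sim_config(duration = 2880))
  t_cst <- simulate_enzyme(p, cst, sim_config(duration = 2880))
  expect_equal(t_ser$product_rate, t_cst$product_rate, tolerance = 1e-4)
})

test_that("product rate series is turnover times bound-substrate concentration", {
  p <- wt_params_for("dasatinib")
  traj <- simulate_enzyme(p, 20, sim_config(duration = 10, out_step = 1))
  expect_equal(product_rate_series(traj),
               p$variant$kcat * traj$states[, "E_AS"])
})
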