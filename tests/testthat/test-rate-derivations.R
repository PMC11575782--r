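test_that("residence time converts to an off-rate by reciprocal", {
  expect_equal(residence_to_koff(17), 0.059, tolerance = 0.01)
  expect_equal(residence_to_koff(205), 0.00488, tolerance = 0.001)
  expect_identical(residence_to_koff(1), 1)
  expect_error(residence_to_koff(0), "> 0")
  expect_error(residence_to_koff(-3), "> 0")
})

test_that("thermodynamic factor follows the configured convention", {
  expect_identical(thermo_factor(thermo_config(), ddG = -2.2), 1)
  expect_identical(thermo_factor(thermo_config(), ddG = 5), 1)
  pm <- thermo_config(dG_WT = -1, convention = "per_mole_RT")
  expect_equal(thermo_factor(pm, ddG = 1), 1)                 # gap of zero
  # direct arithmetic with R = 1.9872e-3 kcal/(mol K), T = 300 K
  expect_equal(thermo_factor(pm, ddG = 0), exp(1 / (1.9872e-3 * 300)))
  expect_equal(thermo_factor(pm, ddG = 0), 5.3516, tolerance = 1e-4)
  expect_error(thermo_factor(pm, ddG = NA_real_), "ddG")
})

test_that("uninhibited state weight is factor * (1 + S/KM)", {
  expect_equal(uninhibited_weight(1, 10, 17), 1 + 10 / 17)
  expect_identical(uninhibited_weight(1, 0, 17), 1)
  expect_identical(uninhibited_weight(2, 10, 10), 4)
  expect_error(uninhibited_weight(1, 10, 0), "KM")
})

test_that("IC50 converts to a dissociation constant per binding mode", {
  w <- uninhibited_weight(1, 10, 17)
  expect_equal(ic50_to_kd(527, "inactive_binder", w), 203.6, tolerance = 1e-3)
  expect_equal(ic50_to_kd(1.8, "active_binder", w, factor = 1), 0.695,
               tolerance = 1e-3)
  # zero weight: the IC50 is the dissociation constant in either mode
  expect_identical(ic50_to_kd(42, "inactive_binder", 0), 42)
  expect_identical(ic50_to_kd(42, "active_binder", 0, factor = 1), 42)
})

test_that("dissociation constant is monotone in IC50 and in the weight", {
  w <- seq(0.5, 20, length.out = 30)
  for (mode in c("inactive_binder", "active_binder")) {
    rd_w <- ic50_to_kd(500, mode, w)
    expect_true(all(diff(rd_w) < 0))
    ic <- seq(1, 5000, length.out = 30)
    rd_ic <- ic50_to_kd(ic, mode, 1.6)
    expect_true(all(diff(rd_ic) > 0))
  }
})

test_that("on-rate follows from off-rate and dissociation constant", {
  expect_equal(kon_from_koff(4.88e-3, 0.811), 6.02e-3, tolerance = 1e-3)
  expect_equal(kon_from_koff(2.33e-3, 0.695), 3.35e-3, tolerance = 1e-3)
  expect_identical(kon_from_koff(0.7, 0.7), 1)
  expect_error(kon_from_koff(0.1, 0), "RD")
})

test_that("substrate rates honour the wild-type and mutant branch rules", {
  wt <- substrate_rates(66, 17)
  expect_equal(wt$koffS, 33)
  expect_equal(wt$konS, 5.82, tolerance = 1e-3)
  expect_identical(wt$branch, "wild_type")

  g250e <- substrate_rates(175.2, 14.3, konS_WT = wt$konS)
  expect_identical(g250e$branch, "mutant")
  expect_equal(g250e$koffS, 350.4)
  expect_equal(g250e$konS, 36.8, tolerance = 2e-3)
  expect_identical(g250e$koffS / 175.2, 2)       # exact in branch 1

  e255v <- substrate_rates(6.8, 22.1, konS_WT = wt$konS)
  expect_identical(e255v$branch, "mutant_fallback")
  expect_identical(e255v$konS, wt$konS)          # exact in the fallback
  expect_equal(e255v$koffS, 122, tolerance = 1e-3)

  # Michaelis relation holds exactly by construction in every branch
  for (r in list(wt, g250e, e255v)) {
    kcat <- c(wild_type = 66, mutant = 175.2, mutant_fallback = 6.8)[[r$branch]]
    KM <- c(wild_type = 17, mutant = 14.3, mutant_fallback = 22.1)[[r$branch]]
    expect_equal((kcat + r$koffS) / r$konS, KM)
  }
})

test_that("inhibitor rates are inherited per binding mode and ATP-site flag", {
  # inactive binder: off-rate fixed at the wild-type value
  wt_pon <- wt_params_for("ponatinib")$inhibitor
  g <- inhibitor_rates("inactive_binder", wt_pon, RD = 12.5 / (2 + 10 / 14.3))
  expect_equal(g$RD, 4.63, tolerance = 1e-3)
  expect_identical(g$koffR, wt_pon$koffR)
  expect_equal(g$konR, 1.05e-3, tolerance = 5e-3)

  # active binder, ATP-site variant: on-rate scaled by the substrate ratio
  wt_das <- wt_params_for("dasatinib")$inhibitor
  ratio <- (3 * 8.1 / 1.9) / (99 / 17)
  t315m <- inhibitor_rates("active_binder", wt_das,
                           RD = 768 / (2 + 10 / 1.9),
                           konS_ratio = ratio, atp_site_mutant = TRUE)
  expect_equal(t315m$konR, 7.37e-3, tolerance = 3e-3)
  expect_equal(t315m$koffR, 0.779, tolerance = 2e-3)

  # active binder, non-ATP-site variant: on-rate equals the wild type's
  e255k <- inhibitor_rates("active_binder", wt_das, RD = 3.9,
                           konS_ratio = 2.1, atp_site_mutant = FALSE)
  expect_identical(e255k$konR, wt_das$konR)

  # unit ratio and wild-type RD reproduce the wild-type rates
  same <- inhibitor_rates("inactive_binder", wt_pon, RD = wt_pon$RD)
  expect_equal(same[c("RD", "konR", "koffR")],
               wt_pon[c("RD", "konR", "koffR")])
})

test_that("conformational rates are 60/min with the documented G250E exception", {
  expect_identical(conformational_rates("Wild-type"),
                   c(ktransA = 60, ktransI = 60))
  expect_identical(conformational_rates("G250E"),
                   c(ktransA = 55, ktransI = 55))
  expect_identical(conformational_rates("T315I"),
                   c(ktransA = 60, ktransI = 60))
})

test_that("mutant free-energy gap is the wild-type gap plus the shift", {
  expect_identical(mutant_dG(-1, -2.2), -3.2)
  expect_identical(mutant_dG(-1, 0), -1)
  expect_identical(mutant_dG(0, 0.4), 0.4)
})

test_that("assembled parameter sets are complete and internally consistent", {
  wt_ima <- wt_params_for("imatinib")
  expect_equal(wt_ima$inhibitor$RD, 203.6, tolerance = 1e-4)
  expect_identical(wt_ima$inhibitor$koffR, 0.059)
  expect_equal(wt_ima$inhibitor$konR, 0.059 / 203.6136, tolerance = 1e-6)

  e255v <- params_for("E255V", "imatinib")
  expect_equal(e255v$inhibitor$RD, 3651, tolerance = 2e-4)

  comp <- params_for("Y253H-E255V", "imatinib")
  expect_equal(comp$substrate$koffS, 26.4)
  expect_equal(comp$substrate$konS, 56.6, tolerance = 1e-3)

  # requesting a drug with no IC50 entry is a configuration error
  v <- enzyme_variant("x", 10, 5, c(imatinib = 100))
  expect_error(build_parameter_set(v, .drugs$dasatinib), "no IC50")
  # a wild-type reference derived for another drug is rejected
  expect_error(params <- build_parameter_set(
    bundle_variant(.bundle, "E255K"), .drugs$imatinib,
    wt_reference = wt_params_for("dasatinib")), "derived for drug")
})

test_that("every derived rate triple satisfies RD * konR = koffR exactly", {
  tab <- derive_parameter_table(.bundle)
  expect_identical(nrow(tab), 21L)
  expect_equal(tab$RD_nM * tab$konR_per_nM_min, tab$koffR_per_min,
               tolerance = 1e-15)
})
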