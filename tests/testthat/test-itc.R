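pre_fusion_exp <- function() {
  itc_experiment(cell_conc = 14e-6, syringe_conc = 210e-6)
}

test_that("displacement correction tracks cell concentrations sensibly", {
  ex <- itc_experiment(cell_conc = 14e-6, syringe_conc = 210e-6,
                       injection_volumes = rep(2e-6, 20))
  conc <- titration_concentrations(ex)
  expect_true(all(diff(conc$macromolecule) < 0))
  expect_true(all(diff(conc$titrant) > 0))
  expect_true(all(conc$macromolecule > 0 & conc$titrant > 0))
  # continuity: a vanishing injection leaves the cell at its loading state
  tiny <- itc_experiment(14e-6, 210e-6, injection_volumes = 1e-12)
  c0 <- titration_concentrations(tiny)
  expect_equal(c0$macromolecule, 14e-6, tolerance = 1e-6)
  expect_equal(c0$titrant, 0, tolerance = 1e-10)
})

test_that("displacement correction agrees with serial mass tracking", {
  # oracle: ideal mixing then overflow of the injected volume, per injection
  ex <- pre_fusion_exp()
  v0 <- ex$cell_volume
  n_m <- ex$cell_conc * v0
  n_x <- 0
  serial_m <- serial_x <- numeric(length(ex$injection_volumes))
  for (i in seq_along(ex$injection_volumes)) {
    dv <- ex$injection_volumes[i]
    n_x <- n_x + ex$syringe_conc * dv
    keep <- v0 / (v0 + dv)
    n_m <- n_m * keep
    n_x <- n_x * keep
    serial_m[i] <- n_m / v0
    serial_x[i] <- n_x / v0
  }
  conc <- titration_concentrations(ex)
  # the two conventions are different discretisations of the same physics
  expect_true(all(rel_diff(conc$macromolecule, serial_m) < 0.01))
  expect_true(all(rel_diff(conc$titrant, serial_x) < 0.01))
})

test_that("overfilling the cell is flagged", {
  expect_warning(
    itc_experiment(14e-6, 210e-6, injection_volumes = rep(20e-6, 15)),
    class = "clampeq_overfill")
})

test_that("cumulative heat equals enthalpy times bound complex", {
  v0 <- 200e-6
  # worked case: Kd 457 nM, 14 uM cell, 7 uM titrant
  q <- one_site_cumulative_heat(457e-9, -10, 1, 14e-6, 7e-6, v0)
  q_oracle <- v0 * -10 * oracle_hetero_bound(14e-6, 7e-6, 457e-9) * 1e9
  expect_lt(rel_diff(q, q_oracle), 1e-8)
  # grid sweep including n != 1 (receptor total is n * Mt)
  for (kd in c(1e-8, 457e-9, 2e-5)) for (xt in c(1e-7, 7e-6, 5e-5)) {
    for (n in c(0.5, 1, 2)) {
      q <- one_site_cumulative_heat(kd, -10, n, 14e-6, xt, v0)
      q_oracle <- v0 * -10 * oracle_hetero_bound(n * 14e-6, xt, kd) * 1e9
      expect_lt(rel_diff(q, q_oracle), 1e-8)
    }
  }
})

test_that("cumulative heat limits hold", {
  v0 <- 200e-6
  expect_identical(one_site_cumulative_heat(457e-9, -10, 1, 14e-6, 0, v0), 0)
  # infinite affinity, titrant beyond saturation: all sites filled
  q_sat <- one_site_cumulative_heat(1e-18, -10, 1, 14e-6, 30e-6, v0)
  expect_equal(q_sat, 1 * 14e-6 * -10 * v0 * 1e9, tolerance = 1e-9)
})

test_that("simulated thermograms have the expected structure", {
  ex <- pre_fusion_exp()
  # zero enthalpy, zero heat
  tg0 <- simulate_thermogram(ex, binding_parameters(457e-9, 0))
  expect_true(all(tg0$heat_ucal == 0))
  # telescoping: per-injection heats sum to the final cumulative heat plus
  # exactly the displaced-volume terms
  tg <- simulate_thermogram(ex, binding_parameters(457e-9, -10))
  q <- tg$cumulative_heat_ucal
  dilution <- (tg$volume_uL * 1e-6 / ex$cell_volume) * (q + c(0, q[-length(q)])) / 2
  expect_equal(sum(tg$heat_ucal), dplyr::last(q) + sum(dilution),
               tolerance = 1e-10)
  # normalized heats share the sign of the enthalpy
  expect_true(all(sign(tg$ndh_kcal_per_mol) == -1))
  tg_pos <- simulate_thermogram(ex, binding_parameters(457e-9, 5))
  expect_true(all(sign(tg_pos$ndh_kcal_per_mol) == 1))
})

test_that("at high c the first injections release the full molar enthalpy", {
  m0 <- 14e-6
  kd <- m0 / 1000  # c = 1000
  ex <- pre_fusion_exp()
  tg <- simulate_thermogram(ex, binding_parameters(kd, -10))
  expect_equal(tg$ndh_kcal_per_mol[2], -10, tolerance = 0.02)
})

test_that("multi-site model reduces to one site and is order-invariant", {
  ex <- pre_fusion_exp()
  one <- simulate_thermogram(ex, binding_parameters(457e-9, -10))
  # single class
  red1 <- simulate_two_site_thermogram(
    ex, tibble::tibble(kd = 457e-9, enthalpy = -10, n = 1))
  expect_equal(red1$ndh_kcal_per_mol, one$ndh_kcal_per_mol, tolerance = 1e-9)
  # second class with zero association drops out
  red2 <- simulate_two_site_thermogram(
    ex, tibble::tibble(kd = c(457e-9, Inf), enthalpy = c(-10, -5), n = c(1, 1)))
  expect_equal(red2$ndh_kcal_per_mol, one$ndh_kcal_per_mol, tolerance = 1e-9)
  # site-class order is irrelevant
  sites <- tibble::tibble(kd = c(457e-9, 2e-6), enthalpy = c(-10, -5), n = c(1, 1))
  a <- simulate_two_site_thermogram(ex, sites)
  b <- simulate_two_site_thermogram(ex, sites[2:1, ])
  expect_equal(a$ndh_kcal_per_mol, b$ndh_kcal_per_mol, tolerance = 1e-12)
})

test_that("multi-site model is continuous in its parameters", {
  ex <- pre_fusion_exp()
  sites <- tibble::tibble(kd = c(457e-9, 2e-6), enthalpy = c(-10, -5), n = c(1, 1))
  bumped <- sites
  bumped$kd[2] <- sites$kd[2] * (1 + 1e-6)
  a <- simulate_two_site_thermogram(ex, sites)
  b <- simulate_two_site_thermogram(ex, bumped)
  expect_lt(max(abs(a$ndh_kcal_per_mol - b$ndh_kcal_per_mol)), 1e-4)
})

test_that("multi-site heat saturates at the sum over classes", {
  # heavy excess: ~36 molar equivalents injected in total
  ex <- itc_experiment(cell_conc = 2e-6, syringe_conc = 300e-6)
  sites <- tibble::tibble(kd = c(5e-8, 5e-7), enthalpy = c(-10, -4), n = c(1, 1))
  tg <- simulate_two_site_thermogram(ex, sites)
  conc <- titration_concentrations(ex)
  q_full <- ex$cell_volume * dplyr::last(conc$macromolecule) *
    sum(sites$n * sites$enthalpy) * 1e9
  expect_equal(dplyr::last(tg$cumulative_heat_ucal), q_full, tolerance = 0.01)
})

test_that("bivalent titration at the unblocked-complex geometry is biphasic", {
  # central-helix class plus a weaker accessory class: the curve cannot be
  # reproduced by any one-set-of-sites isotherm
  ex <- itc_experiment(cell_conc = 7.5e-6, syringe_conc = 150e-6)
  sites <- tibble::tibble(kd = c(457e-9, 2e-6), enthalpy = c(-8, -6), n = c(1, 1))
  tg <- simulate_two_site_thermogram(ex, sites)
  fit <- suppressWarnings(fit_one_site(tg, ex))
  expect_gt(fit$sigma, 10 * .Machine$double.eps)
  one <- simulate_thermogram(ex, fit$parameters)
  expect_gt(max(abs(one$ndh_kcal_per_mol - tg$ndh_kcal_per_mol)), 0.01)
})

test_that("noise-free fits recover the generating parameters", {
  ex <- pre_fusion_exp()
  truth <- binding_parameters(457e-9, -10, n = 1)
  tg <- simulate_thermogram(ex, truth)
  fit <- fit_one_site(tg, ex)
  expect_lt(rel_diff(fit$parameters$kd, truth$kd), 1e-6)
  expect_lt(rel_diff(fit$parameters$enthalpy, truth$enthalpy), 1e-6)
  expect_lt(rel_diff(fit$parameters$n, truth$n), 1e-6)
  expect_false(fit$c_warning)
  # fixed-stoichiometry variant
  fit2 <- fit_one_site(tg, ex, fix_n = 1)
  expect_lt(rel_diff(fit2$parameters$kd, truth$kd), 1e-6)
  # tidy/glance expose the derived thermodynamics
  td <- tidy(fit)
  expect_setequal(td$term, c("n", "enthalpy", "ka", "kd", "delta_G", "T_delta_S"))
  expect_equal(td$estimate[td$term == "delta_G"],
               binding_thermodynamics(fit$parameters$kd)$delta_G)
  expect_true(glance(fit)$converged)
})

test_that("low-c titrations are flagged, not silently accepted", {
  ex <- itc_experiment(cell_conc = 20e-6, syringe_conc = 360e-6)
  tg <- simulate_thermogram(ex, binding_parameters(23.9e-6, -10))
  expect_warning(fit_one_site(tg, ex, fix_n = 1), class = "clampeq_c_value")
})

test_that("fitter recovery bias is small across the identifiable c range", {
  # property sweep: 1% noise, c spanning two orders of magnitude
  for (cval in c(5, 50, 500)) {
    m0 <- 14e-6
    kd <- m0 / cval
    ex <- pre_fusion_exp()
    truth <- binding_parameters(kd, -10)
    study <- itc_recovery_study(truth, ex, noise_fraction = 0.01,
                                replicates = 300, seed = 101 + cval)
    expect_lt(rel_diff(geomean(study$kd), kd), 0.02)
    expect_lt(rel_diff(mean(study$enthalpy), -10), 0.02)
  }
})
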