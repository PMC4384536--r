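test_that("free energy from affinity matches the thermodynamic relations", {
  # ln(1) = 0 at Kd = 1 M
  expect_equal(binding_thermodynamics(1)$delta_G, 0)
  # frozen values computed independently as -(1.987e-3)(298.15) ln(1/Kd)
  expect_equal(binding_thermodynamics(1e-6)$delta_G, -8.1846, tolerance = 1e-4)
  expect_equal(binding_thermodynamics(43e-9)$delta_G, -10.0487, tolerance = 1e-4)
  # decomposition holds by construction
  th <- binding_thermodynamics(457e-9, enthalpy = -10)
  expect_equal(th$delta_G, th$delta_H - th$T_delta_S)
})

test_that("affinity round-trips through the free energy", {
  for (kd in 10^seq(-12, -2, by = 2)) {
    for (temp in c(277.15, 298.15, 310.15)) {
      dg <- binding_thermodynamics(kd, temperature = temp)$delta_G
      ka_back <- exp(-dg / (1.987e-3 * temp))
      expect_equal(ka_back, 1 / kd, tolerance = 1e-9)
    }
  }
})

test_that("invalid thermodynamic inputs are rejected", {
  expect_error(binding_thermodynamics(-1e-6), class = "clampeq_invalid_parameter")
  expect_error(binding_thermodynamics(0), class = "clampeq_invalid_parameter")
  expect_error(binding_thermodynamics(1e-6, temperature = 0),
               class = "clampeq_invalid_parameter")
  expect_error(bound_complex(-1e-6, 1e-6, 1e-6),
               class = "clampeq_invalid_parameter")
  expect_error(self_association(-1e-6, 1e-6),
               class = "clampeq_invalid_parameter")
})

test_that("heterodimer solver handles limits and the blocked-complex case", {
  expect_equal(bound_complex(0, 1e-6, 1e-6), 0)
  # stoichiometric limit: infinitely tight binding saturates the limiting species
  expect_equal(bound_complex(1e-6, 1e-6, 1e-18), 1e-6, tolerance = 1e-6)
  # 20 uM receptor, 30 uM ligand, Kd 457 nM (frozen from the bisection oracle)
  expect_equal(bound_complex(20e-6, 30e-6, 0.457e-6), 19.189e-6,
               tolerance = 1e-4)
})

test_that("closed-form solvers agree with bisection on a log-grid", {
  grid <- 10^seq(-12, -2, by = 2.5)
  for (R in grid) for (L in grid) for (kd in grid) {
    b <- bound_complex(R, L, kd)
    expect_lt(rel_diff(b, oracle_hetero_bound(R, L, kd)), 1e-9)
    expect_lte(b, min(R, L) * (1 + 1e-12))
  }
  for (C in grid) for (kd in grid) {
    sa <- self_association(C, kd)
    expect_lt(rel_diff(sa$unbound, oracle_self_unbound(C, kd)), 1e-9)
    expect_identical(sa$unbound + sa$bound, C)  # conservation, exact
  }
})

test_that("bound concentration is monotone in totals and affinity", {
  R <- 10^seq(-7, -4, length.out = 8)
  expect_true(all(diff(bound_complex(R, 1e-5, 1e-6)) > 0))
  expect_true(all(diff(bound_complex(1e-5, R, 1e-6)) > 0))
  kds <- 10^seq(-9, -4, length.out = 8)
  expect_true(all(diff(bound_complex(1e-5, 1e-5, kds)) < 0))
})

test_that("blocking saturation behaves as a titration of the central-helix site", {
  # 1.5-fold excess of the blocking fragment occupies ~96% of sites at 20 uM
  expect_equal(saturation_percent(20e-6, 1.5, 457e-9), 95.944, tolerance = 1e-4)
  # 3-fold excess pushes occupancy near 99%
  expect_equal(saturation_percent(20e-6, 3, 457e-9), 98.877, tolerance = 1e-4)
  # infinite affinity saturates completely
  expect_equal(saturation_percent(20e-6, 1.5, 1e-18), 100, tolerance = 1e-9)
  # strictly increasing in excess and in R/kd
  ex <- seq(0.5, 4, by = 0.5)
  expect_true(all(diff(saturation_percent(20e-6, ex, 457e-9)) > 0))
  rr <- 10^seq(-6, -4, length.out = 6)
  expect_true(all(diff(saturation_percent(rr, 1.5, 457e-9)) > 0))
})

test_that("self-association splits concentration as the quadratic dictates", {
  expect_equal(unlist(self_association(0, 25e-6)[, c("unbound", "bound")]),
               c(unbound = 0, bound = 0))
  # at C = Kd the unbound fraction is (sqrt(5) - 1)/2 of C
  sa <- self_association(25e-6, 25e-6)
  expect_equal(sa$unbound, 25e-6 * (sqrt(5) - 1) / 2, tolerance = 1e-12)
  # strong excess drives everything into the bound pool
  sa2 <- self_association(1, 1e-9)
  expect_gt(sa2$bound / 1, 0.9999)
})

test_that("fold change divides affinities", {
  expect_identical(fold_change(16e-6, 2e-6), 8)
  expect_identical(fold_change(3e-6, 3e-6), 1)
  expect_equal(fold_change(457e-9, 43e-9), 10.628, tolerance = 1e-4)
  expect_error(fold_change(0, 1e-6), class = "clampeq_invalid_parameter")
})
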