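test_that("species potential: neutral pore is the linear voltage ramp", {
  tp <- transport_problem()
  w0 <- species_potential(tp, "cation", 0)
  expect_true(all(w0$values == 0))
  kT <- 1.380649e-23 * 298
  w <- species_potential(tp, "cation", 0.1)
  expect_equal(w$values[length(w$values)], 0)
  expect_equal(w$values[1], 1.602176634e-19 * 0.1 / kT, tolerance = 1e-12)
  # anion landscape is the charge-conjugate at any voltage
  wa <- species_potential(tp, "anion", 0.1)
  expect_equal(wa$values, -w$values)
})

test_that("a negative ring is a well for cations and a barrier for anions", {
  tp <- transport_problem(charges = list(lumen_charge(5, -1, 7)))
  wc <- species_potential(tp, "cation", 0)
  wa <- species_potential(tp, "anion", 0)
  mid <- which.min(abs(wc$grid - 5))
  expect_equal(which.min(wc$values), mid)
  expect_equal(which.max(wa$values), mid)
  expect_equal(wc$values, -wa$values)
})

test_that("potentials beyond +/-50 kT are clipped with a warning", {
  tp <- transport_problem(charges = list(lumen_charge(5, -5, 7)),
                          well_screening_length = 50, bjerrum_length = 50)
  expect_warning(w <- species_potential(tp, "cation", 0), "clip")
  expect_true(all(abs(w$values) <= 50))
})

test_that("neutral pore conducts exactly at the bulk-cylinder (ohmic) limit", {
  tp <- transport_problem()
  g_ideal <- bulk_conductance(tp$geometry, tp$electrolyte)
  v <- seq(-0.2, 0.2, length.out = 41)
  iv <- iv_curve(tp, v)
  expect_lt(max(abs(iv$currents - g_ideal * v)) / max(abs(iv$currents)), 1e-6)
})

test_that("current vanishes at V = 0 for arbitrary charge sets", {
  for (s in 1:5) {
    tp <- random_problem(seed = s)
    expect_equal(steady_state_current(tp, 0), 0)
  }
})

test_that("exact symmetries: charge conjugation + voltage reversal; mirror", {
  for (s in 1:5) {
    tp <- random_problem(seed = s)
    v <- 0.13
    expect_equal(steady_state_current(tp, v),
                 -steady_state_current(conjugate_problem(tp), -v),
                 tolerance = 1e-12)
    # mirror reflection: IV curve is the point reflection of the original
    ivm <- iv_curve(mirror_problem(tp), c(-v, 0, v))
    iv <- iv_curve(tp, c(-v, 0, v))
    expect_equal(iv$currents[3], -ivm$currents[1], tolerance = 1e-10)
  }
})

test_that("rectification factor: formula, bounds and symmetric-pore null", {
  iv_lin <- new_iv_curve(c(-0.2, 0.2), c(-1e-10, 1e-10))
  expect_equal(rectification_factor(iv_lin), 0)
  iv2 <- new_iv_curve(c(-0.1, 0, 0.1), c(-50e-12, 0, 150e-12))
  expect_equal(rectification_factor(iv2), 0.5)
  # a mirror-symmetric charge set has an odd IV curve, hence beta = 0,
  # whereas an antisymmetric (bipolar-diode) set rectifies
  tp <- transport_problem(
    charges = list(lumen_charge(3, 1, 7), lumen_charge(7, 1, 7)),
    elec = electrolyte(1, diffusion_coefficient_cation = 2e-9,
                       diffusion_coefficient_anion = 2e-9))
  expect_lt(abs(rectification_factor(iv_curve(tp, c(-0.1, 0, 0.1)))), 1e-10)
  bipolar <- transport_problem(
    charges = list(lumen_charge(3, 1, 7), lumen_charge(7, -1, 7)),
    elec = electrolyte(1, diffusion_coefficient_cation = 2e-9,
                       diffusion_coefficient_anion = 2e-9))
  expect_gt(abs(rectification_factor(iv_curve(bipolar, c(-0.1, 0, 0.1)))), 0.05)
})

test_that("concentration profiles: bulk at rest, Boltzmann enrichment, flux asymmetry", {
  tp0 <- transport_problem()
  pr <- concentration_profile(tp0, "cation", 0)
  expect_equal(pr$concentration, rep(1, length(pr$grid)))
  # cation-attracting well enriches cations and depletes anions at V = 0
  tp <- transport_problem(charges = list(lumen_charge(5, -1, 7)))
  cc <- concentration_profile(tp, "cation", 0)$concentration
  ca <- concentration_profile(tp, "anion", 0)$concentration
  expect_gt(mean(cc), 1)
  expect_lt(mean(ca), 1)
  # with a field, the cation excess shifts downstream of the well and the
  # accumulation side flips with the voltage sign
  ccp <- concentration_profile(tp, "cation", 0.1)$concentration
  ccm <- concentration_profile(tp, "cation", -0.1)$concentration
  grid <- concentration_profile(tp, "cation", 0.1)$grid
  up <- grid < 4.5; dn <- grid > 5.5
  excess_p <- mean(ccp[dn]) - mean(ccp[up])
  excess_m <- mean(ccm[dn]) - mean(ccm[up])
  expect_gt(excess_p, excess_m)
})

test_that("charge position scan: mouth charges matter less; composed mirror symmetry", {
  tp0 <- transport_problem()
  L <- tp0$geometry$length
  b <- charge_position_scan(tp0, -1, c(0, 0.15 * L, 0.85 * L, L))
  expect_lt(abs(b[1]), abs(b[2]))
  expect_lt(abs(b[4]), abs(b[3]))
  # beta(z; q) = beta(L - z; -q) under equal diffusivities
  tpe <- transport_problem(elec = electrolyte(
    1, diffusion_coefficient_cation = 2e-9, diffusion_coefficient_anion = 2e-9))
  z <- c(1.5, 3.7, 8.1)
  expect_equal(charge_position_scan(tpe, 1, z),
               charge_position_scan(tpe, -1, L - z), tolerance = 1e-8)
  # zero valence leaves the base problem untouched
  expect_equal(charge_position_scan(tp0, 0, z), rep(0, 3), tolerance = 1e-12)
})

test_that("conductance is non-increasing as a same-sign barrier pair grows", {
  elec <- electrolyte(1, diffusion_coefficient_cation = 2e-9,
                      diffusion_coefficient_anion = 2e-9)
  g <- sapply(1:7, function(m) {
    tp <- transport_problem(charges = list(lumen_charge(4.5, 1, m),
                                           lumen_charge(5.5, 1, m)),
                            elec = elec)
    steady_state_current(tp, 0.02) / 0.02
  })
  expect_true(all(diff(g) <= 1e-15))
})

test_that("currents are continuous in voltage across a dense sweep", {
  tp <- wt_problem()
  iv <- iv_curve(tp, seq(-0.2, 0.2, length.out = 401))
  expect_true(all(is.finite(iv$currents)))
  jumps <- abs(diff(iv$currents))
  expect_lt(max(jumps), 5 * stats::median(jumps) + 1e-15)
})

test_that("grid refinement is converged at the default resolution", {
  tp <- wt_problem()
  i1 <- steady_state_current(tp, 0.15)
  tp$n_grid <- 2L * tp$n_grid
  i2 <- steady_state_current(tp, 0.15)
  expect_lt(abs(i1 - i2) / abs(i2), 1e-6)
})

test_that("pore config JSON round trip preserves the problem", {
  tp <- wt_problem()
  path <- withr::local_tempfile(fileext = ".json")
  write_pore_config(tp, path)
  tp2 <- read_pore_config(path)
  expect_equal(steady_state_current(tp2, 0.1), steady_state_current(tp, 0.1))
})

test_that("invalid geometry and charges are rejected", {
  expect_error(pore_geometry(-1, 10), "positive")
  expect_error(pore_geometry(5, 2), "longer")
  expect_error(lumen_charge(3, 0), "non-zero")
  expect_error(transport_problem(charges = list(lumen_charge(15, -1))),
               "outside")
  expect_error(species_potential(wt_problem(), "cation", 1.5), "<= 1")
})
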