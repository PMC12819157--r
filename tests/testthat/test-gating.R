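test_that("closing rate: zero below V_c, zero at wrong polarity, e-fold growth", {
  rm <- rate_model("negative", critical_voltage = 0.1, closing_prefactor = 2,
                   closing_efold_voltage = 0.03)
  expect_equal(closing_rate_at(rm, -0.09), 0)
  expect_equal(closing_rate_at(rm, 0.2), 0)     # positive sign never closes
  expect_equal(closing_rate_at(rm, -(0.1 + 0.03)), 2 * exp(1))
  # polarity both with independent thresholds
  rb <- rate_model("both", critical_voltage = c(negative = 0.08, positive = 0.15),
                   closing_prefactor = 1, closing_efold_voltage = 0.05)
  expect_gt(closing_rate_at(rb, -0.1), 0)
  expect_equal(closing_rate_at(rb, 0.1), 0)
  expect_gt(closing_rate_at(rb, 0.2), 0)
})

test_that("reopening requires a small voltage on the non-closing side", {
  rm <- rate_model("negative", opening_rate = 10, reopening_window = 0.15,
                   release_voltage = 0.06)
  expect_equal(opening_rate_at(rm, -0.09), 0)   # closing-sign bias holds shut
  expect_equal(opening_rate_at(rm, -0.05), 10)  # below the release voltage
  expect_equal(opening_rate_at(rm, 0), 10)
  expect_equal(opening_rate_at(rm, 0.11), 10)
  expect_equal(opening_rate_at(rm, 0.2), 0)     # outside the window
})

test_that("closed-probability ODE matches closed forms at constant voltage", {
  rm <- rate_model("negative", critical_voltage = 0.1, closing_prefactor = 1,
                   closing_efold_voltage = 0.04, opening_rate = 0)
  prot <- make_protocol("constant", baseline = -0.16, duration = 2,
                        sample_rate = 1000)
  k <- closing_rate_at(rm, -0.16)
  sol <- closed_probability_ode(rm, prot, p0 = 0)
  expect_equal(sol$p, 1 - exp(-k * sol$time), tolerance = 1e-6)
  # sub-critical voltage: p stays at p0
  prot2 <- make_protocol("constant", baseline = -0.05, duration = 2,
                         sample_rate = 1000)
  sol2 <- closed_probability_ode(rm, prot2, p0 = 0.3)
  expect_equal(sol2$p, rep(0.3, length(sol2$p)), tolerance = 1e-9)
})

test_that("Monte Carlo ensemble mean matches the ODE within binomial error", {
  rm <- rate_model()
  # dt refinement is the accuracy knob of the Bernoulli stepping; 1 kHz keeps
  # the stepping bias at the fast reopening edge well below the binomial band
  prot <- make_protocol("fig2c", sample_rate = 1000)
  iv <- wt_open_iv()
  n <- 2000
  tr <- simulate_ensemble(n, rm, closed_state_distribution(), iv, prot,
                          seed = 42)
  p_mc <- tr$metadata$truth$p_true
  sol <- closed_probability_ode(rm, prot, p0 = 0)
  se <- sqrt(pmax(sol$p * (1 - sol$p), 1 / n) / n)
  z <- abs(p_mc - sol$p) / se
  # pointwise binomial band; the extreme of ~10^4 correlated points is
  # allowed a modestly wider excursion
  expect_gt(mean(z < 3), 0.99)
  expect_lt(max(z), 5)
})

test_that("non-gating ensembles are exact multiples of the open IV", {
  rm0 <- rate_model("none")
  iv <- wt_open_iv()
  prot <- make_protocol("fig2a", sample_rate = 2000)
  tr1 <- simulate_ensemble(1, rm0, closed_state_distribution(), iv, prot,
                           noise_sd = 0, seed = 1)
  expected <- iv_interpolate(iv, tr1$voltage)
  expect_equal(tr1$current, expected)
  trN <- simulate_ensemble(7, rm0, closed_state_distribution(), iv, prot,
                           noise_sd = 0, seed = 1)
  expect_equal(trN$current, 7 * expected)
})

test_that("simulations are bit-reproducible by seed and differ across seeds", {
  iv <- wt_open_iv()
  prot <- make_protocol("fig2c", sample_rate = 500, duration = 20)
  a <- simulate_ensemble(10, rate_model(), closed_state_distribution(), iv,
                         prot, noise_sd = 1e-12, seed = 5)
  b <- simulate_ensemble(10, rate_model(), closed_state_distribution(), iv,
                         prot, noise_sd = 1e-12, seed = 5)
  c <- simulate_ensemble(10, rate_model(), closed_state_distribution(), iv,
                         prot, noise_sd = 1e-12, seed = 6)
  expect_identical(a$current, b$current)
  expect_false(identical(a$current, c$current))
})

test_that("gated-state conductance draws are diverse across events", {
  iv <- wt_open_iv()
  prot <- make_protocol("fig2c", sample_rate = 500, duration = 100)
  tr <- simulate_ensemble(30, rate_model(), closed_state_distribution(), iv,
                          prot, seed = 9)
  eps <- tr$metadata$truth$epsilon_draws
  expect_gt(length(eps), 200)
  expect_lt(abs(sd(eps) - 0.05) / 0.05, 0.2)
  expect_true(all(eps > 0 & eps < 1))
})

test_that("point-mass epsilon bounds the normalized ensemble current", {
  iv <- wt_open_iv()
  prot <- make_protocol("fig2c", sample_rate = 500, duration = 20)
  n <- 12
  tr <- simulate_ensemble(n, rate_model(), closed_state_distribution(0.14, 0),
                          iv, prot, noise_sd = 0, seed = 3)
  io <- iv_interpolate(iv, tr$voltage)
  sel <- abs(io) > 1e-13
  ratio <- tr$current[sel] / (n * io[sel])
  expect_true(all(ratio >= 0.14 - 1e-9 & ratio <= 1 + 1e-9))
})

test_that("hysteresis requires gating: loop area vanishes at high frequency", {
  iv <- wt_open_iv()
  rm <- rate_model()
  loop_area <- function(freq) {
    prot <- make_protocol("sinusoid", amplitude = 0.2, frequency = freq,
                          sample_rate = 500 * freq, duration = 1 / freq)
    tr <- simulate_ensemble(40, rm, closed_state_distribution(0.14, 0), iv,
                            prot, noise_sd = 0, seed = 21)
    # signed area of the I(V) loop via the shoelace formula
    abs(sum(tr$voltage * c(tail(tr$current, -1), tr$current[1]) -
            tr$current * c(tail(tr$voltage, -1), tr$voltage[1])) / 2)
  }
  # the loop is largest at intermediate frequency (gating spread over the
  # sweep) and collapses when the cycle is much faster than the rates
  slow <- loop_area(1)
  fast <- loop_area(100)
  expect_lt(fast, 0.1 * slow)
  # and with all rates zero there is no loop at all
  prot <- make_protocol("fig2c", sample_rate = 500)
  tr0 <- simulate_ensemble(40, rate_model("none"), closed_state_distribution(),
                           iv, prot, noise_sd = 0, seed = 21)
  a0 <- abs(sum(tr0$voltage * c(tail(tr0$current, -1), tr0$current[1]) -
                tr0$current * c(tail(tr0$voltage, -1), tr0$voltage[1])) / 2)
  expect_lt(a0, 1e-6 * slow)
})

test_that("negative gater shows hysteresis only at negative polarity, pinched at origin", {
  iv <- wt_open_iv()
  prot <- make_protocol("fig2c", sample_rate = 500, duration = 100)
  tr <- simulate_ensemble(26, rate_model(), closed_state_distribution(), iv,
                          prot, noise_sd = 2e-12, seed = 2)
  cs <- segment_cycles(tr, prot)
  # mean loop: compare rising vs falling branch current at +/-0.15 V
  v <- cs$voltage; icur <- colMeans(cs$currents)
  rising <- c(diff(abs(v)), 0) > 0
  at <- function(target, br) {
    idx <- which(br & (if (target > 0) v > 0 else v < 0))
    stats::approx(v[idx], icur[idx], xout = target)$y
  }
  gap_neg <- abs(at(-0.15, rising) - at(-0.15, !rising))
  gap_pos <- abs(at(0.15, rising) - at(0.15, !rising))
  expect_gt(gap_neg, 10 * gap_pos)
  i0 <- icur[which.min(abs(v))]
  expect_lt(abs(i0), 3 * 2e-12)
})

test_that("simulation refuses protocols outside the IV span", {
  iv <- iv_curve(wt_problem(), seq(-0.1, 0.1, length.out = 21))
  prot <- make_protocol("fig2c")
  expect_error(simulate_ensemble(5, rate_model(), closed_state_distribution(),
                                 iv, prot, seed = 1), "span")
})
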