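# Closed-form model mathematics: integration constant, dynamic amplitude,
# perturbation solution, trend and noise-regime schedule.

test_that("integration constant inverts the a0-gamma relation", {
  # growing-amplitude case: 1/(4k) = 1/a0^2 - 1/gamma^2
  k <- integration_constant(0.5, 4.6416)
  expect_equal(1 / (4 * k), 3.95359, tolerance = 1e-5)
  expect_true(k > 0)
  # decaying-amplitude case (a0 > gamma) flips the sign
  k2 <- integration_constant(2.7760, 1.2618)
  expect_equal(1 / (4 * k2), -0.498319, tolerance = 1e-5)
  expect_true(k2 < 0)
  # constant-amplitude case: infinite-k sentinel
  expect_identical(integration_constant(3, 3), Inf)
  expect_error(integration_constant(-1, 2), "positive")
  expect_error(integration_constant(1, 0), "positive")
})

test_that("dynamic amplitude reproduces published worked values", {
  # four fitted animal-phase parameter sets with known end-of-phase
  # amplitudes, printed to 4 decimals (inputs rounded to 4 decimals)
  cases <- list(
    list(p = vdp_params(0.5000, 4.6416, 0.4969), t = 144, a = 4.6416),
    list(p = vdp_params(2.7760, 1.2618, 0.2000), t = 144, a = 1.2620),
    list(p = vdp_params(3.8264, 1.4968, 0.2000), t = 144, a = 1.4971),
    list(p = vdp_params(0.9150, 3.8367, 0.2000), t = 240, a = 3.8363))
  for (cs in cases)
    expect_equal(amplitude_at(cs$t, cs$p), cs$a, tolerance = 1e-3)
})

test_that("amplitude function satisfies its boundary and limit laws", {
  set.seed(11)
  for (i in 1:1000) {
    p <- vdp_params(runif(1, 0.05, 8), runif(1, 0.05, 8),
                    runif(1, 0.05, 1.5), runif(1, -pi, pi))
    expect_equal(amplitude_at(0, p), p$a0, tolerance = 1e-12)
  }
  # monotone approach to the limit cycle
  p_up <- vdp_params(0.5, 3, 0.3)
  p_dn <- vdp_params(4, 1.5, 0.3)
  p_eq <- vdp_params(2, 2, 0.3)
  tt <- seq(0, 200, by = 0.5)
  expect_true(all(diff(amplitude_at(tt, p_up)) > 0))
  expect_true(all(diff(amplitude_at(tt, p_dn)) < 0))
  expect_equal(amplitude_at(tt, p_eq), rep(2, length(tt)))
  # convergence to gamma within 144 h: at the epsilon lower bound 0.2 the
  # residual transient is below 1e-3 for start/limit ratios within a
  # factor 2 (fitted-animal scale); for epsilon >= 0.4 even a factor-10
  # mismatch has fully decayed
  set.seed(12)
  for (i in 1:50) {
    gam <- runif(1, 0.5, 5)
    p <- vdp_params(gam * runif(1, 0.5, 2), gam, runif(1, 0.2, 1))
    expect_lt(abs(amplitude_at(144, p) - gam) / gam, 1e-3)
    p2 <- vdp_params(gam * runif(1, 0.1, 10), gam, runif(1, 0.4, 1))
    expect_lt(abs(amplitude_at(144, p2) - gam) / gam, 1e-3)
  }
  expect_error(amplitude_at(-1, p_up), "non-negative")
})

test_that("amplitude obeys its differential equation to leading order", {
  p <- vdp_params(0.8, 3, 0.2)
  om <- omega_of(p)
  tt <- seq(1, 100, by = 1)
  h <- 1e-4
  num <- (amplitude_at(tt + h, p) - amplitude_at(tt - h, p)) / (2 * h)
  a <- amplitude_at(tt, p)
  ana <- p$epsilon * a * om / 2 * (1 - a^2 / p$gamma^2)
  expect_lt(max(abs(num - ana) / abs(ana)), 1e-2)
})

test_that("perturbation solution reduces to a cosine at epsilon zero and
           matches hand evaluation otherwise", {
  p0 <- vdp_params(2, 2, 0, 0)
  tt <- seq(0, 96, by = 0.05)
  expect_equal(circadian_component(tt, p0),
               2 * cos(2 * pi / 24 * tt), tolerance = 1e-14)
  expect_equal(circadian_component(0, p0), 2)
  expect_equal(circadian_component(6, p0), 0, tolerance = 1e-12)
  # hand-evaluated value: 3cos(pi/6) - 0.2*27/(8*9)*sin(pi/2)
  p <- vdp_params(3, 3, 0.2, 0)
  expect_equal(circadian_component(2, p), 2.52308, tolerance = 1e-5)
  # constant-amplitude option freezes the leading term at a0
  p2 <- vdp_params(0.5, 3, 0.3, 0)
  x_dyn <- circadian_component(48, p2)
  x_const <- circadian_component(48, p2, dynamic_amplitude = FALSE)
  expect_false(isTRUE(all.equal(x_dyn, x_const)))
})

test_that("trend and model mean evaluate affinely", {
  expect_equal(trend_at(0, trend_params(30.0259, 0.0002)), 30.0259)
  expect_equal(trend_at(10, trend_params(1, 0)), 1)
  expect_equal(trend_at(100, trend_params(1e-9 + 0, 0.5)), 50,
               tolerance = 1e-6)
  fm <- full_model_params(vdp_params(2, 2, 0, 0), trend_params(30),
                          noise_params(1, 1, 1))
  expect_equal(model_mean(0, fm), 32)
  expect_equal(model_mean(12, fm), 28)
  fm2 <- full_model_params(vdp_params(3, 3, 0.2, 0), trend_params(30),
                           noise_params(1, 1, 1))
  expect_equal(model_mean(2, fm2), 32.52308, tolerance = 1e-5)
})

test_that("noise regimes partition the day with left-closed boundaries", {
  r <- regime_of(c(6, 12, 3, 11.99, 17.99, 18, 0, 23.9))
  expect_equal(as.character(r),
               c("day1", "day2", "night", "day1", "day2", "night",
                 "night", "night"))
  # every clock time maps to exactly one regime
  grid <- seq(0, 23.95, by = 0.05)
  expect_false(anyNA(regime_of(grid)))
  # clock times wrap modulo 24
  expect_equal(as.character(regime_of(30)), "day1")
})

test_that("parameter containers validate their invariants", {
  expect_error(vdp_params(0, 1, 0.5), "a0")
  expect_error(vdp_params(1, 1, 0.5, psi = 4), "psi")
  expect_error(trend_params(-1), "c0")
  expect_error(noise_params(1, -1, 1), "positive")
  expect_error(variance_schedule(12, 6, 18), "ordered")
})
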