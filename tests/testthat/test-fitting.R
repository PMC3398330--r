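# Pseudo-maximum-likelihood fitting: trend, starting values, likelihood,
# variance profiling, bounds, the full optimiser and diagnostics.

test_that("trend regression recovers exact and noisy linear baselines", {
  t <- seq(0, 143.95, by = 0.05)
  flat <- temperature_series(t, rep(30, length(t)))
  expect_equal(fit_trend(flat)$c0, 30)
  expect_equal(fit_trend(flat)$c1, 0)
  lin <- temperature_series(t, 30 + 0.01 * t)
  tr <- fit_trend(lin)
  expect_equal(tr$c0, 30, tolerance = 1e-10)
  expect_equal(tr$c1, 0.01, tolerance = 1e-10)
  # sampling check: OLS SEs at n=2880, sigma^2 ~ 5
  set.seed(21)
  noisy <- temperature_series(t, 30 + 0.002 * t + rnorm(length(t), 0, sqrt(5)))
  tr2 <- fit_trend(noisy)
  se_c1 <- sqrt(5 / sum((t - mean(t))^2))
  expect_lt(abs(tr2$c1 - 0.002), 3 * se_c1)
  se_c0 <- sqrt(5 * (1 / length(t) + mean(t)^2 / sum((t - mean(t))^2)))
  expect_lt(abs(tr2$c0 - 30), 3 * se_c0)
})

test_that("harmonic initialisation recovers amplitude and phase", {
  t <- seq(0, 23.95, by = 0.05)
  om <- 2 * pi / 24
  h <- harmonic_init(t, 2 * cos(om * t))
  expect_equal(h$amplitude, 2, tolerance = 1e-10)
  expect_equal(h$psi, 0, tolerance = 1e-10)
  # 2 sin(om t) = 2 cos(om t - pi/2)
  h2 <- harmonic_init(t, 2 * sin(om * t))
  expect_equal(h2$amplitude, 2, tolerance = 1e-10)
  expect_equal(h2$psi, -pi / 2, tolerance = 1e-10)
  # noisy day: amplitude within 3 SE (SE = sqrt(2*sigma^2/n))
  set.seed(8)
  y <- 3 * cos(om * t + 0.4) + rnorm(length(t), 0, 2)
  h3 <- harmonic_init(t, y)
  expect_lt(abs(h3$amplitude - 3), 3 * sqrt(2 * 4 / length(t)))
  expect_lt(abs(h3$psi - 0.4), 0.2)
  expect_error(harmonic_init(t[t < 12], y[t < 12]), "full period")
})

test_that("negative log-likelihood matches closed forms and the dense
           multivariate-normal oracle", {
  # closed form: N residuals of 1 at unit variance give N*(log(2*pi)+1)/2
  t4 <- seq(0, 3)
  p <- full_model_params(vdp_params(0.001, 0.001, 0, 0),
                         trend_params(29), noise_params(1, 1, 1))
  s4 <- temperature_series(t4, 29 + 0.001 * cos(2 * pi / 24 * t4) + 1)
  nll <- negative_log_likelihood(s4, p)
  expect_equal(nll, 4 * (0.5 * log(2 * pi) + 0.5), tolerance = 1e-3)
  # oracle equivalence on 100 random small instances
  for (i in 1:100) {
    inst <- random_small_instance(n = sample(4:20, 1), seed = i)
    v <- regime_variance(regime_of(clock_time(inst$series)),
                         inst$params$noise)
    oracle <- dense_mvn_nll(inst$series$temperature,
                            model_mean(inst$series$time_h, inst$params),
                            diag(v))
    expect_equal(negative_log_likelihood(inst$series, inst$params), oracle,
                 tolerance = 1e-10)
  }
})

test_that("variance profiling is the per-regime mean square with a floor", {
  reg <- factor(rep(c("day1", "day2", "night"), each = 4),
                levels = c("day1", "day2", "night"))
  r <- c(rep(0, 4), -1, 1, -1, 1, rep(2, 4))
  np <- profile_variances(r, reg)
  expect_equal(np$var_day1, 1e-6)  # floored
  expect_equal(np$var_day2, 1)
  expect_equal(np$var_night, 4)
  expect_error(profile_variances(1:3, factor(c("day1", "day1", "day2"),
                                             levels = c("day1", "day2", "night"))),
               "night")
  # sampling bound: 1e4 draws at sigma^2 = 7 land within ~3 SE
  set.seed(4)
  big <- rnorm(3e4, 0, sqrt(7))
  regb <- factor(rep(c("day1", "day2", "night"), 1e4),
                 levels = c("day1", "day2", "night"))
  npb <- profile_variances(big, regb)
  expect_lt(abs(npb$var_night - 7), 0.3)
})

test_that("amplitude bounds are half the first/last-day spans", {
  t <- seq(0, 143.95, by = 0.05)
  y <- rep(32, length(t))
  y[t < 24] <- 28 + 8 * (t[t < 24] / 24)          # first day spans [28, 36]
  y[t >= 120] <- 30 + 3 * ((t[t >= 120] - 120) / 24)  # last day spans [30, 33]
  s <- temperature_series(t, y)
  b <- compute_bounds(s)
  expect_equal(b$a0_upper, 4, tolerance = 1e-2)
  expect_equal(b$gamma_upper, 1.5, tolerance = 1e-2)
  short <- temperature_series(seq(0, 11.95, by = 0.05),
                              rnorm(240, 30))
  expect_error(compute_bounds(short), "full day")
  flat <- temperature_series(t, rep(30, length(t)))
  expect_error(fit_phase(flat), "degenerate")
})

test_that("amplitude bounds exceed the truth in simulated studies", {
  # simulation audit over seeded replicates of the default scenario scale
  truth <- make_truth()
  ok <- vapply(1:50, function(i) {
    s <- simulate_phase(truth, study_design(), "P2", seed = 400 + i)
    b <- compute_bounds(s)
    b$a0_upper > 1.4 && b$gamma_upper > 2.7
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("fit recovers parameters from quiet simulations", {
  truth <- make_quiet_truth(a0 = 0.5, gamma = 3, epsilon = 0.4, psi = 0,
                            c0 = 30, c1 = 0)
  s <- simulate_phase(truth, study_design(), "P3", seed = 77)
  f <- fit_phase(s)
  expect_lt(abs(f$params$vdp$gamma - 3), 0.1)
  expect_lt(abs(f$params$vdp$a0 - 0.5), 0.1)
  expect_lt(abs(f$params$vdp$psi - 0), 0.05)
  expect_true(f$params$vdp$epsilon >= 0.2 && f$params$vdp$epsilon <= 1)
  expect_true(abs(f$params$vdp$psi) <= pi)
})

test_that("constant-amplitude series keep start and limit amplitudes close
           without spurious growth", {
  truth <- make_quiet_truth(a0 = 2, gamma = 2, epsilon = 0.4, psi = 0,
                            c0 = 30, c1 = 0)
  s <- simulate_phase(truth, study_design(), "P2", seed = 55)
  f <- fit_phase(s)
  expect_lt(abs(f$params$vdp$a0 - f$params$vdp$gamma), 0.2)
  expect_lt(abs(f$params$vdp$gamma - 2), 0.1)
})

test_that("fit is stable under perturbed starting values", {
  truth <- make_truth(a0 = 0.8, gamma = 2.5, epsilon = 0.4,
                      psi = 0.2, c0 = 30, c1 = 0, v = c(0.3, 0.3, 0.3))
  s <- simulate_phase(truth, study_design(), "P2", seed = 13)
  base <- fit_phase(s)
  cfg <- fit_config()
  set.seed(14)
  deltas <- replicate(5, {
    init <- base$init + rnorm(4, 0, sqrt(0.1))
    init[1] <- min(max(init[1], cfg$amp_lower), base$bounds$upper[1])
    init[2] <- min(max(init[2], cfg$amp_lower), base$bounds$upper[2])
    init[3] <- min(max(init[3], 0.2), 1)
    init[4] <- min(max(init[4], -pi), pi)
    cfg2 <- fit_config(a0_init_P1 = init[1], epsilon_init = init[3])
    f2 <- fit_phase(s, cfg2, phase_label = "P1")
    est <- c(f2$params$vdp$a0, f2$params$vdp$gamma,
             f2$params$vdp$epsilon, f2$params$vdp$psi)
    ref <- c(base$params$vdp$a0, base$params$vdp$gamma,
             base$params$vdp$epsilon, base$params$vdp$psi)
    mean(abs(est - ref))
  })
  expect_lt(median(deltas), 1e-2)
})

test_that("fit respects pseudo-ML structure: monotone improvement,
           profiling consistency and the a(T) identity", {
  truth <- make_truth()
  for (seed in c(101, 102, 103)) {
    s <- simulate_phase(truth, study_design(), "P2", seed = seed)
    f <- fit_phase(s)
    expect_lte(f$negloglik, f$nll_init)
    # re-profiled variances at the optimum equal the reported ones
    reprof <- profile_variances(f$residuals, f$regime)
    expect_equal(reprof$var_day1, f$params$noise$var_day1)
    expect_equal(reprof$var_night, f$params$noise$var_night)
    expect_equal(f$a_at_T, amplitude_at(f$T_end, f$params$vdp))
    # trend equals the fixed least-squares estimate
    expect_equal(f$params$trend$c0, fit_trend(s)$c0)
  }
})

test_that("outer-loop profiling mode agrees with per-evaluation profiling", {
  truth <- make_truth()
  s <- simulate_phase(truth, study_design(), "P2", seed = 301)
  f1 <- fit_phase(s)
  f2 <- fit_phase(s, fit_config(profile_every_eval = FALSE))
  expect_lt(abs(f1$params$vdp$gamma - f2$params$vdp$gamma), 0.05)
  expect_lt(abs(f1$negloglik - f2$negloglik), 1)
})

test_that("AIC follows its formula and favours the dynamic model on
           adapting-amplitude data", {
  truth <- make_truth()
  s <- simulate_phase(truth, study_design(), "P2", seed = 201)
  f <- fit_phase(s)
  expect_equal(aic(f), 2 * 9 + 2 * f$negloglik)
  expect_equal(aic(f, p = 10) - aic(f), 2)
  # loglik -6000 with 9 parameters
  fake <- f; fake$negloglik <- 6000
  expect_equal(aic(fake), 12018)
  # growing-amplitude series: dynamic model beats the constant-amplitude
  # harmonic regression
  grow <- make_truth(a0 = 0.5, gamma = 3.5, epsilon = 0.3, v = c(4, 2, 4))
  sg <- simulate_phase(grow, study_design(), "P3", seed = 202)
  fg <- fit_phase(sg)
  harm <- fit_harmonic_reference(sg)
  expect_lt(fg$aic, harm$aic)
})

test_that("residual autocorrelations behave for known processes", {
  truth <- make_truth()
  s <- simulate_phase(truth, study_design(), "P2", seed = 501)
  f <- fit_phase(s)
  ac <- residual_acf(f, max_lag = 20)
  # white-noise band: most lags inside 3.5/sqrt(n)
  expect_gte(mean(abs(ac) < 3.5 / sqrt(f$n)), 0.95)
  # injected AR(1) residuals show up at lag 1
  set.seed(502)
  ar <- as.numeric(arima.sim(list(ar = 0.5), n = f$n))
  f2 <- f; f2$residuals <- ar
  ac1 <- residual_acf(f2, max_lag = 5)[["lag1"]]
  expect_lt(abs(ac1 - 0.5), 0.05)
  f3 <- f; f3$residuals <- rep(1, f$n)
  expect_error(residual_acf(f3), "constant")
  expect_error(residual_acf(f, max_lag = f$n), "below")
})
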