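# Pseudo-maximum-likelihood estimation of the full observation model for
# one animal-phase series: trend by ordinary least squares (then fixed),
# period fixed at 24 h, regime variances profiled from residuals at every
# objective evaluation, and the four oscillator parameters (a0, gamma,
# epsilon, psi) optimised by bounded quasi-Newton (L-BFGS-B).

#' Fitting configuration
#'
#' @param tau_fixed Circadian period held fixed during optimisation, hours
#'   (default 24, matching a 12:12 light-dark entrainment).
#' @param epsilon_bounds Box constraint for the flexibility parameter. The
#'   lower bound of 0.2 prevents degenerate fits in which an inflated
#'   limit-cycle amplitude is compensated by a vanishing epsilon; the
#'   upper bound of 1 keeps the perturbation solution close to the exact
#'   oscillator.
#' @param psi_bounds Box constraint for the phase shift, radians.
#' @param a0_init_P1 Start-amplitude initial value used in the first
#'   experimental phase (default 0.5 degC), promoting small start
#'   amplitudes right after surgery.
#' @param amp_lower Lower box bound for both amplitudes, degC.
#' @param epsilon_init Initial flexibility (default 0.5, box midpoint).
#' @param var_floor Variance floor protecting the likelihood when a regime's
#'   residuals degenerate, degC^2.
#' @param reltol Relative convergence tolerance on the objective.
#' @param maxit Maximum optimiser iterations.
#' @param profile_every_eval If `TRUE` (default) regime variances are
#'   re-profiled at every objective evaluation (profile likelihood); if
#'   `FALSE` they are re-profiled once per outer optimisation round until
#'   the profiled objective stabilises.
#' @return An object of class `"fit_config"`.
#' @export
fit_config <- function(tau_fixed = 24, epsilon_bounds = c(0.2, 1),
                       psi_bounds = c(-pi, pi), a0_init_P1 = 0.5,
                       amp_lower = 0.05, epsilon_init = 0.5,
                       var_floor = 1e-6, reltol = 1e-8, maxit = 500L,
                       profile_every_eval = TRUE) {
  stopifnot(tau_fixed > 0, length(epsilon_bounds) == 2L,
            epsilon_bounds[1] < epsilon_bounds[2],
            length(psi_bounds) == 2L, psi_bounds[1] < psi_bounds[2],
            amp_lower > 0, var_floor > 0, reltol > 0, maxit >= 1)
  structure(list(tau_fixed = tau_fixed, epsilon_bounds = epsilon_bounds,
                 psi_bounds = psi_bounds, a0_init_P1 = a0_init_P1,
                 amp_lower = amp_lower, epsilon_init = epsilon_init,
                 var_floor = var_floor, reltol = reltol,
                 maxit = as.integer(maxit),
                 profile_every_eval = isTRUE(profile_every_eval)),
            class = "fit_config")
}

#' Linear baseline trend by ordinary least squares
#'
#' Regresses temperature on hours since phase start. The estimates are
#' held fixed in the subsequent oscillator optimisation.
#'
#' @param series A [temperature_series()].
#' @return A [trend_params()] object.
#' @export
fit_trend <- function(series) {
  stopifnot(inherits(series, "temperature_series"))
  t <- series$time_h
  if (length(unique(t)) < 2L) stop("cannot fit a trend to a constant time vector")
  co <- stats::coef(stats::lm(series$temperature ~ t))
  structure(list(c0 = unname(co[1L]), c1 = unname(co[2L])),
            class = "trend_params")
}

#' Harmonic-regression starting values for amplitude and phase
#'
#' Least-squares fit of `A1*cos(omega*t) + A2*sin(omega*t)` to a
#' (detrended) window spanning at least one full period; amplitude
#' `sqrt(A1^2 + A2^2)` and phase `-atan2(A2, A1)` (so that the fitted wave
#' equals `a*cos(omega*t + psi)`) seed the nonlinear optimisation.
#'
#' @param time_h Sample times in hours (from phase start; the window need
#'   not start at 0).
#' @param y Detrended temperatures for the window, degC.
#' @param tau Period in hours (default 24).
#' @return List with elements `amplitude` and `psi` (wrapped to
#'   `[-pi, pi]`).
#' @export
#' @examples
#' t <- seq(0, 23.95, by = 0.05)
#' harmonic_init(t, 2 * cos(2 * pi / 24 * t))  # amplitude 2, psi 0
harmonic_init <- function(time_h, y, tau = 24) {
  stopifnot(is.numeric(time_h), is.numeric(y), length(time_h) == length(y))
  dt <- stats::median(diff(time_h))
  if (diff(range(time_h)) < tau - dt - 1e-9)
    stop("harmonic initialisation needs a window spanning a full period")
  om <- 2 * pi / tau
  X <- cbind(cos(om * time_h), sin(om * time_h))
  co <- stats::coef(stats::lm.fit(X, y))
  a <- sqrt(sum(co^2))
  psi <- atan2(-co[2L], co[1L])  # wraps to (-pi, pi] by construction
  list(amplitude = unname(a), psi = unname(psi))
}

#' Negative log-likelihood of a series under the full model
#'
#' Multivariate-normal negative log-likelihood with a diagonal covariance
#' holding the regime variance of each sample:
#' `N/2 log(2*pi) + 1/2 sum(log sigma^2_n) + 1/2 sum(r_n^2 / sigma^2_n)`
#' with residuals `r_n = y_n - x(t_n) - c(t_n)`.
#'
#' @param series A [temperature_series()].
#' @param params A [full_model_params()].
#' @param schedule A [variance_schedule()] mapping clock times to regimes.
#' @return The negative log-likelihood in nats.
#' @export
negative_log_likelihood <- function(series, params,
                                    schedule = variance_schedule()) {
  stopifnot(inherits(series, "temperature_series"),
            inherits(params, "full_model_params"))
  v <- regime_variance(regime_of(clock_time(series), schedule), params$noise)
  r <- series$temperature - model_mean(series$time_h, params)
  n <- length(r)
  n / 2 * log(2 * pi) + sum(log(v)) / 2 + sum(r^2 / v) / 2
}

#' Profile the regime variances from residuals
#'
#' Maximum-likelihood variance of the residuals in each noise regime
#' (mean of squared residuals, divisor `n`), floored to protect the
#' likelihood from degenerate regimes.
#'
#' @param residuals Numeric residuals, degC.
#' @param regime Factor of regimes (`day1`, `day2`, `night`) per residual,
#'   as returned by [regime_of()].
#' @param floor Variance floor, degC^2.
#' @return A [noise_params()] object.
#' @export
profile_variances <- function(residuals, regime, floor = 1e-6) {
  stopifnot(is.numeric(residuals), length(residuals) == length(regime))
  regime <- factor(regime, levels = c("day1", "day2", "night"))
  counts <- table(regime)
  if (any(counts < 2L))
    stop("regime(s) with fewer than 2 residuals: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  ms <- tapply(residuals^2, regime, mean)
  v <- pmax(as.numeric(ms), floor)
  noise_params(v[1L], v[2L], v[3L])
}

#' Data-driven upper bounds for the amplitudes
#'
#' Half the span of raw temperatures during the first day bounds the start
#' amplitude; half the span during the last day bounds the limit-cycle
#' amplitude.
#'
#' @param series A [temperature_series()] covering at least one full day.
#' @return List with elements `a0_upper` and `gamma_upper`, degC.
#' @export
compute_bounds <- function(series) {
  stopifnot(inherits(series, "temperature_series"))
  t <- series$time_h
  if (diff(range(t)) < 24 - series$delta_t_h - 1e-9)
    stop("amplitude bounds need at least one full day of data")
  first <- series$temperature[t < t[1L] + 24]
  last <- series$temperature[t >= t[length(t)] - 24 + series$delta_t_h / 2]
  list(a0_upper = diff(range(first)) / 2,
       gamma_upper = diff(range(last)) / 2)
}

# per-regime index lists for fast profiling inside the objective
regime_index <- function(series, schedule) {
  split(seq_along(series$time_h),
        regime_of(clock_time(series), schedule))
}

# profiled negative log-likelihood given detrended data; regime index
# lists precomputed. Returns the NLL with variances set to the per-regime
# mean squared residual (floored).
profiled_nll <- function(par, t, ydet, idx, om, var_floor,
                         fixed_noise = NULL) {
  a0 <- par[1L]; gam <- par[2L]; eps <- par[3L]; psi <- par[4L]
  inv4k <- 1 / a0^2 - 1 / gam^2
  a <- (inv4k * exp(-eps * om * t) + 1 / gam^2)^(-0.5)
  x <- a * cos(om * t + psi) -
    eps * a^3 / (8 * gam^2) * sin(3 * om * t + 3 * psi)
  r2 <- (ydet - x)^2
  nll <- length(t) / 2 * log(2 * pi)
  for (j in seq_along(idx)) {
    i <- idx[[j]]
    v <- if (is.null(fixed_noise)) max(mean(r2[i]), var_floor)
         else fixed_noise[j]
    nll <- nll + length(i) / 2 * log(v) + sum(r2[i]) / (2 * v)
  }
  nll
}

#' Fit the dynamic van der Pol model to one animal-phase series
#'
#' Pseudo-maximum-likelihood fit: (1) the linear trend is estimated by
#' least squares and fixed; (2) the period is fixed at
#' `config$tau_fixed`; (3) the remaining four oscillator parameters are
#' optimised by L-BFGS-B inside data-driven boxes, with the three regime
#' variances profiled from the current residuals at every objective
#' evaluation; (4) starting values come from one-day harmonic regressions
#' (first day for the start amplitude and phase, last day for the
#' limit-cycle amplitude), except that the start amplitude is initialised
#' at `config$a0_init_P1` in the first experimental phase.
#'
#' @param series A [temperature_series()] with at least one full day of
#'   samples.
#' @param config A [fit_config()].
#' @param phase_label Phase label controlling the start-amplitude
#'   initialisation rule; defaults to the series' own phase. The special
#'   initial value applies when the label is the design's first phase
#'   (`"P1"`).
#' @param schedule A [variance_schedule()].
#' @return An object of class `"phase_fit"`: estimated
#'   [full_model_params()], negative log-likelihood, AIC, amplitude at
#'   phase end `a_at_T`, the boxes and initial values used, a convergence
#'   flag and the residuals with their regimes.
#' @export
#' @examples
#' truth <- full_model_params(vdp_params(0.5, 3, 0.4, 0),
#'                            trend_params(30), noise_params(4, 2, 4))
#' s <- simulate_phase(truth, study_design(), "P3", seed = 42)
#' fit <- fit_phase(s)
#' fit$params$vdp$gamma  # close to 3
fit_phase <- function(series, config = fit_config(),
                      phase_label = series$phase,
                      schedule = variance_schedule()) {
  stopifnot(inherits(series, "temperature_series"),
            inherits(config, "fit_config"))
  t <- series$time_h
  y <- series$temperature
  om <- 2 * pi / config$tau_fixed

  trend <- fit_trend(series)
  ydet <- y - trend_at(t, trend)

  bounds <- compute_bounds(series)
  if (bounds$a0_upper <= config$amp_lower ||
      bounds$gamma_upper <= config$amp_lower)
    stop("degenerate series: first/last-day span too small to bound amplitudes")

  # harmonic starting values on detrended first/last day
  in_first <- t < t[1L] + 24
  in_last <- t >= t[length(t)] - 24 + series$delta_t_h / 2
  h_first <- harmonic_init(t[in_first], ydet[in_first], config$tau_fixed)
  h_last <- harmonic_init(t[in_last], ydet[in_last], config$tau_fixed)

  clip <- function(x, lo, hi) min(max(x, lo), hi)
  a0_init <- if (identical(phase_label, "P1")) config$a0_init_P1
             else h_first$amplitude
  init <- c(a0 = clip(a0_init, config$amp_lower, bounds$a0_upper),
            gamma = clip(h_last$amplitude, config$amp_lower,
                         bounds$gamma_upper),
            epsilon = clip(config$epsilon_init, config$epsilon_bounds[1L],
                           config$epsilon_bounds[2L]),
            psi = clip(h_first$psi, config$psi_bounds[1L],
                       config$psi_bounds[2L]))
  lower <- c(config$amp_lower, config$amp_lower,
             config$epsilon_bounds[1L], config$psi_bounds[1L])
  upper <- c(bounds$a0_upper, bounds$gamma_upper,
             config$epsilon_bounds[2L], config$psi_bounds[2L])

  idx <- regime_index(series, schedule)
  idx <- idx[lengths(idx) > 0L]

  run_optim <- function(par0, fixed_noise = NULL) {
    stats::optim(par0, profiled_nll, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = config$maxit,
                                factr = config$reltol / .Machine$double.eps),
                 t = t, ydet = ydet, idx = idx, om = om,
                 var_floor = config$var_floor, fixed_noise = fixed_noise)
  }

  nll_init <- profiled_nll(init, t, ydet, idx, om, config$var_floor)
  if (config$profile_every_eval) {
    opt <- run_optim(init)
    converged <- opt$convergence == 0L
  } else {
    # outer loop: alternate fixed-variance optimisation with re-profiling
    par0 <- init
    prev <- Inf
    converged <- FALSE
    for (round in 1:25) {
      vfix <- vapply(idx, function(i) {
        max(mean(profiled_resid(par0, t, ydet, om)[i]^2), config$var_floor)
      }, numeric(1L))
      opt <- run_optim(par0, fixed_noise = vfix)
      cur <- profiled_nll(opt$par, t, ydet, idx, om, config$var_floor)
      par0 <- opt$par
      if (is.finite(prev) && abs(prev - cur) <= config$reltol * (abs(cur) + 1)) {
        converged <- TRUE
        break
      }
      prev <- cur
    }
    opt$value <- profiled_nll(par0, t, ydet, idx, om, config$var_floor)
    opt$par <- par0
  }

  # guarantee monotone improvement over the starting point
  if (opt$value > nll_init) {
    opt$par <- init
    opt$value <- nll_init
    converged <- FALSE
  }

  est <- opt$par
  vdp <- vdp_params(est[1L], est[2L], est[3L], est[4L], config$tau_fixed)
  regime <- regime_of(clock_time(series), schedule)
  resid <- ydet - circadian_component(t, vdp)
  noise <- profile_variances(resid, regime, config$var_floor)
  params <- full_model_params(vdp, trend, noise)
  nll <- negative_log_likelihood(series, params, schedule)
  T_end <- t[length(t)]

  structure(list(params = params, negloglik = nll,
                 aic = 2 * 9 + 2 * nll, n_free_params = 9L,
                 a_at_T = amplitude_at(T_end, vdp), T_end = T_end,
                 bounds = list(lower = lower, upper = upper),
                 init = init, nll_init = nll_init,
                 convergence = converged,
                 residuals = resid, regime = regime,
                 animal_id = series$animal_id, group = series$group,
                 phase = series$phase, n = length(y),
                 time_unit = "hours since phase start"),
            class = "phase_fit")
}

# residuals of the circadian component for a raw parameter vector
profiled_resid <- function(par, t, ydet, om) {
  a0 <- par[1L]; gam <- par[2L]; eps <- par[3L]; psi <- par[4L]
  inv4k <- 1 / a0^2 - 1 / gam^2
  a <- (inv4k * exp(-eps * om * t) + 1 / gam^2)^(-0.5)
  ydet - (a * cos(om * t + psi) -
            eps * a^3 / (8 * gam^2) * sin(3 * om * t + 3 * psi))
}

#' @export
print.phase_fit <- function(x, ...) {
  cat(sprintf("van der Pol phase fit: animal %s, phase %s (n = %d)\n",
              x$animal_id, x$phase, x$n))
  v <- x$params$vdp
  cat(sprintf("  a0 = %.4f, gamma = %.4f, epsilon = %.4f, psi = %.4f\n",
              v$a0, v$gamma, v$epsilon, v$psi))
  cat(sprintf("  a(T) = %.4f degC at T = %.0f h\n", x$a_at_T, x$T_end))
  cat(sprintf("  NLL = %.2f, AIC = %.2f, converged: %s\n",
              x$negloglik, x$aic, x$convergence))
  invisible(x)
}

#' Akaike information criterion of a phase fit
#'
#' `AIC = 2p + 2*NLL`. The default parameter count is 9: the four
#' optimised oscillator parameters plus two trend coefficients and three
#' profiled variances, with the period fixed. Set `p = 10` to count the
#' period as well.
#'
#' @param fit A [phase_fit()] object (from [fit_phase()]).
#' @param p Number of free parameters.
#' @return The AIC value.
#' @export
aic <- function(fit, p = 9L) {
  stopifnot(inherits(fit, "phase_fit"))
  2 * p + 2 * fit$negloglik
}

#' Harmonic-regression reference fit
#'
#' Constant-amplitude sinusoidal baseline `c0 + c1*t + A1*cos(omega*t) +
#' A2*sin(omega*t)` fitted by least squares with the same regime-variance
#' profiling, used as the AIC comparison baseline for the dynamic model.
#'
#' @param series A [temperature_series()].
#' @param tau Period in hours.
#' @param schedule A [variance_schedule()].
#' @return List with the coefficients, negative log-likelihood and `aic`
#'   (7 free parameters: two trend, two harmonic, three variances).
#' @export
fit_harmonic_reference <- function(series, tau = 24,
                                   schedule = variance_schedule()) {
  stopifnot(inherits(series, "temperature_series"))
  t <- series$time_h
  om <- 2 * pi / tau
  fit <- stats::lm(series$temperature ~ t + cos(om * t) + sin(om * t))
  resid <- stats::residuals(fit)
  regime <- regime_of(clock_time(series), schedule)
  noise <- profile_variances(resid, regime)
  v <- regime_variance(regime, noise)
  nll <- length(t) / 2 * log(2 * pi) + sum(log(v)) / 2 + sum(resid^2 / v) / 2
  list(coefficients = stats::coef(fit), negloglik = nll, aic = 2 * 7 + 2 * nll)
}

#' Residual autocorrelation of a phase fit
#'
#' Sample autocorrelations of the fitted residuals, pooled or within one
#' noise regime, for judging the independence assumption of the noise.
#'
#' @param fit A fitted `phase_fit`.
#' @param max_lag Largest lag in samples; must be below the series length.
#' @param regime Optional regime label (`"day1"`, `"day2"`, `"night"`) to
#'   restrict to; `NULL` pools all residuals.
#' @return Named numeric vector of autocorrelations at lags `1..max_lag`.
#' @export
residual_acf <- function(fit, max_lag = 20L, regime = NULL) {
  stopifnot(inherits(fit, "phase_fit"))
  r <- fit$residuals
  if (!is.null(regime)) {
    regime <- match.arg(regime, c("day1", "day2", "night"))
    r <- r[fit$regime == regime]
  }
  if (max_lag >= length(r)) stop("'max_lag' must be below the residual count")
  if (stats::sd(r) == 0) stop("autocorrelation undefined for constant residuals")
  ac <- stats::acf(r, lag.max = max_lag, plot = FALSE)$acf[-1L]
  stats::setNames(as.numeric(ac), paste0("lag", seq_len(max_lag)))
}
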