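# Closed-form mathematics of the dynamic van der Pol circadian model:
# parameter containers, the perturbation-solution circadian component with
# its dynamic amplitude, the linear baseline trend, and the time-of-day
# noise-regime schedule.

#' Van der Pol oscillator parameters
#'
#' Container for the five parameters of the circadian component: start
#' amplitude, limit-cycle amplitude, flexibility, phase shift and period.
#' The oscillation frequency `omega = 2*pi/tau` (rad/hour) and the
#' integration constant `k` of the amplitude function are derived
#' quantities, available through [omega_of()] and [integration_constant()].
#'
#' @param a0 Start amplitude `a(0)` in degrees Celsius; must be positive.
#' @param gamma Limit-cycle amplitude in degrees Celsius; must be positive.
#' @param epsilon Dimensionless flexibility parameter governing the speed
#'   of amplitude adaptation and the deviation from a pure sinusoid. Must
#'   be non-negative; fitted values are box-constrained to `[0.2, 1]`, but
#'   wider values are accepted here for simulation and validation.
#' @param psi Angular phase shift in radians, in `[-pi, pi]`.
#' @param tau Circadian period in hours (default 24).
#'
#' @return An object of class `"vdp_params"`.
#' @seealso [amplitude_at()], [circadian_component()]
#' @export
#' @examples
#' p <- vdp_params(a0 = 0.5, gamma = 4.64, epsilon = 0.5, psi = 0)
#' amplitude_at(144, p)
vdp_params <- function(a0, gamma, epsilon, psi = 0, tau = 24) {
  stopifnot(is.numeric(a0), is.numeric(gamma), is.numeric(epsilon),
            is.numeric(psi), is.numeric(tau), length(a0) == 1L,
            length(gamma) == 1L, length(epsilon) == 1L, length(psi) == 1L,
            length(tau) == 1L)
  if (!is.finite(a0) || a0 <= 0)
    stop("'a0' must be a positive, finite start amplitude (degrees C)")
  if (!is.finite(gamma) || gamma <= 0)
    stop("'gamma' must be a positive, finite limit-cycle amplitude (degrees C)")
  if (!is.finite(epsilon) || epsilon < 0)
    stop("'epsilon' must be a non-negative flexibility parameter")
  if (!is.finite(psi) || psi < -pi || psi > pi)
    stop("'psi' must be an angular phase shift in [-pi, pi]")
  if (!is.finite(tau) || tau <= 0)
    stop("'tau' must be a positive period in hours")
  structure(list(a0 = unname(a0), gamma = unname(gamma),
                 epsilon = unname(epsilon), psi = unname(psi),
                 tau = unname(tau)),
            class = "vdp_params")
}

#' @export
print.vdp_params <- function(x, ...) {
  cat("van der Pol parameters:\n")
  cat(sprintf("  a0 = %.4f degC, gamma = %.4f degC, epsilon = %.4f, psi = %.4f rad, tau = %g h\n",
              x$a0, x$gamma, x$epsilon, x$psi, x$tau))
  invisible(x)
}

#' Angular frequency of a parameter set
#'
#' @param params A [vdp_params()] object.
#' @return `2*pi/tau` in radians per hour.
#' @export
omega_of <- function(params) 2 * pi / params$tau

#' Integration constant of the amplitude function
#'
#' The dynamic amplitude `a(t) = (1/(4k) * exp(-epsilon*omega*t) +
#' 1/gamma^2)^(-1/2)` carries a constant of integration `k` fixed by the
#' start amplitude through `1/(4k) = 1/a0^2 - 1/gamma^2`. `k` is positive
#' when the amplitude grows towards the limit cycle (`a0 < gamma`),
#' negative when it decays (`a0 > gamma`), and infinite in the
#' constant-amplitude case `a0 == gamma`, for which `Inf` is returned and
#' interpreted downstream as `a(t) == gamma` for all `t`.
#'
#' @param a0 Start amplitude, degrees Celsius (positive).
#' @param gamma Limit-cycle amplitude, degrees Celsius (positive).
#' @return The scalar `k` (dimensionless); `Inf` when `a0 == gamma`.
#' @export
#' @examples
#' integration_constant(0.5, 4.6416)   # growing amplitude, k > 0
#' integration_constant(2.776, 1.2618) # decaying amplitude, k < 0
integration_constant <- function(a0, gamma) {
  if (!is.numeric(a0) || length(a0) != 1L || !is.finite(a0) || a0 <= 0)
    stop("'a0' must be a single positive amplitude")
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("'gamma' must be a single positive amplitude")
  inv4k <- 1 / a0^2 - 1 / gamma^2
  if (inv4k == 0) return(Inf)
  1 / (4 * inv4k)
}

# reciprocal form 1/(4k); zero encodes the constant-amplitude case and
# avoids the infinite-k sentinel in arithmetic
inv_four_k <- function(a0, gamma) 1 / a0^2 - 1 / gamma^2

#' Dynamic amplitude of the circadian oscillation
#'
#' Evaluates the closed-form amplitude function
#' `a(t) = (1/(4k) * exp(-epsilon*omega*t) + 1/gamma^2)^(-1/2)`, the
#' solution (up to second order in `epsilon`) of the amplitude equation
#' `da/dt = epsilon*a*omega/2 * (1 - a^2/gamma^2)`. It equals `a0` at
#' `t = 0` and converges monotonically to `gamma` as `t` grows (for
#' `epsilon > 0`).
#'
#' @param t Time since phase start in hours; vectorised, must be
#'   non-negative.
#' @param params A [vdp_params()] object.
#' @return Amplitudes in degrees Celsius, same length as `t`.
#' @export
#' @examples
#' p <- vdp_params(a0 = 2.776, gamma = 1.2618, epsilon = 0.2, psi = 0.4)
#' amplitude_at(c(0, 144), p)  # decays from 2.776 towards 1.2618
amplitude_at <- function(t, params) {
  stopifnot(inherits(params, "vdp_params"), is.numeric(t))
  if (any(t < 0)) stop("'t' must be non-negative (hours since phase start)")
  om <- omega_of(params)
  inv4k <- inv_four_k(params$a0, params$gamma)
  (inv4k * exp(-params$epsilon * om * t) + 1 / params$gamma^2)^(-0.5)
}

#' Circadian component of the temperature signal
#'
#' The second-order perturbation solution of the van der Pol equation:
#' `x(t) = a(t)*cos(omega*t + psi) -
#'   epsilon*a(t)^3/(8*gamma^2) * sin(3*omega*t + 3*psi)`,
#' with the order-`epsilon^2` remainder discarded. For `epsilon = 0` this
#' reduces exactly to the harmonic oscillation `a0*cos(omega*t + psi)`.
#'
#' @param t Time since phase start in hours; vectorised, non-negative.
#' @param params A [vdp_params()] object.
#' @param dynamic_amplitude Logical; if `TRUE` (default) the leading
#'   cosine term carries the dynamic amplitude `a(t)`, matching the cubed
#'   `a(t)` of the harmonic-correction term. `FALSE` freezes the leading
#'   amplitude at `a0` (the literal constant-amplitude reading).
#' @return The circadian component in degrees Celsius.
#' @export
circadian_component <- function(t, params, dynamic_amplitude = TRUE) {
  stopifnot(inherits(params, "vdp_params"), is.numeric(t))
  if (any(t < 0)) stop("'t' must be non-negative (hours since phase start)")
  om <- omega_of(params)
  a <- amplitude_at(t, params)
  lead <- if (dynamic_amplitude) a else params$a0
  lead * cos(om * t + params$psi) -
    params$epsilon * a^3 / (8 * params$gamma^2) *
      sin(3 * om * t + 3 * params$psi)
}

#' Linear trend parameters
#'
#' Baseline intercept and slope of the non-oscillatory temperature trend
#' `c(t) = c0 + c1 * t`, with `t` in hours since phase start.
#'
#' @param c0 Baseline temperature at phase start, degrees Celsius
#'   (positive).
#' @param c1 Linear slope, degrees Celsius per hour (any real).
#' @return An object of class `"trend_params"`.
#' @export
trend_params <- function(c0, c1 = 0) {
  stopifnot(is.numeric(c0), is.numeric(c1), length(c0) == 1L,
            length(c1) == 1L, is.finite(c0), is.finite(c1))
  if (c0 <= 0) stop("'c0' must be a positive baseline temperature")
  structure(list(c0 = c0, c1 = c1), class = "trend_params")
}

#' Evaluate the linear trend
#'
#' @param t Time in hours since phase start; vectorised.
#' @param trend A [trend_params()] object.
#' @return `c0 + c1 * t`, degrees Celsius.
#' @export
trend_at <- function(t, trend) {
  stopifnot(inherits(trend, "trend_params"), is.numeric(t))
  trend$c0 + trend$c1 * t
}

#' Time-of-day noise variances
#'
#' The observational noise is independent normal with a variance that
#' depends on the time of day: a morning regime (husbandry and treatment
#' disturbances), a quiet afternoon regime, and a night regime of
#' increased activity.
#'
#' @param var_day1 Variance for the 06:00-12:00 regime, squared degrees
#'   Celsius.
#' @param var_day2 Variance for the 12:00-18:00 regime.
#' @param var_night Variance for the 18:00-06:00 regime.
#' @return An object of class `"noise_params"`.
#' @export
noise_params <- function(var_day1, var_day2, var_night) {
  v <- c(var_day1, var_day2, var_night)
  stopifnot(is.numeric(v), length(v) == 3L)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all three regime variances must be strictly positive")
  structure(list(var_day1 = var_day1, var_day2 = var_day2,
                 var_night = var_night),
            class = "noise_params")
}

#' Daily variance-regime schedule
#'
#' Partitions the 24-hour day into the three noise regimes by clock time,
#' using half-open, left-closed intervals: `[day1_start, day2_start)` is
#' `day1`, `[day2_start, night_start)` is `day2`, and the remainder of the
#' day is `night`.
#'
#' @param day1_start,day2_start,night_start Regime boundaries as clock
#'   hours in `[0, 24)`; defaults 6, 12 and 18.
#' @return An object of class `"variance_schedule"`.
#' @export
variance_schedule <- function(day1_start = 6, day2_start = 12,
                              night_start = 18) {
  b <- c(day1_start, day2_start, night_start)
  stopifnot(is.numeric(b), length(b) == 3L, all(is.finite(b)))
  if (any(b < 0 | b >= 24)) stop("regime boundaries must be clock hours in [0, 24)")
  if (!(day1_start < day2_start && day2_start < night_start))
    stop("regime boundaries must be ordered day1 < day2 < night start")
  structure(list(day1_start = day1_start, day2_start = day2_start,
                 night_start = night_start),
            class = "variance_schedule")
}

#' Noise regime of a clock time
#'
#' @param clock_time Time of day in hours, `[0, 24)`; vectorised. Values
#'   outside the range are reduced modulo 24.
#' @param schedule A [variance_schedule()] object (default boundaries
#'   06:00/12:00/18:00).
#' @return A factor with levels `day1`, `day2`, `night`.
#' @export
#' @examples
#' regime_of(c(6, 12, 3, 17.95, 18))
regime_of <- function(clock_time, schedule = variance_schedule()) {
  stopifnot(is.numeric(clock_time), inherits(schedule, "variance_schedule"))
  ct <- clock_time %% 24
  r <- ifelse(ct >= schedule$day1_start & ct < schedule$day2_start, "day1",
       ifelse(ct >= schedule$day2_start & ct < schedule$night_start, "day2",
              "night"))
  factor(r, levels = c("day1", "day2", "night"))
}

# regime variance lookup, vectorised over a regime factor
regime_variance <- function(regime, noise) {
  unname(c(day1 = noise$var_day1, day2 = noise$var_day2,
           night = noise$var_night)[as.character(regime)])
}

#' Full observation-model parameters
#'
#' Bundles the oscillator, trend and noise parameters of the observation
#' model `y_n = x(n*dt) + c(n*dt) + e_n` (10 scalar parameters in total).
#'
#' @param vdp A [vdp_params()] object.
#' @param trend A [trend_params()] object.
#' @param noise A [noise_params()] object.
#' @return An object of class `"full_model_params"`.
#' @export
full_model_params <- function(vdp, trend, noise) {
  stopifnot(inherits(vdp, "vdp_params"), inherits(trend, "trend_params"),
            inherits(noise, "noise_params"))
  structure(list(vdp = vdp, trend = trend, noise = noise),
            class = "full_model_params")
}

#' @export
print.full_model_params <- function(x, ...) {
  print(x$vdp)
  cat(sprintf("  trend: c0 = %.4f degC, c1 = %.6f degC/h\n",
              x$trend$c0, x$trend$c1))
  cat(sprintf("  variances: day1 = %.4f, day2 = %.4f, night = %.4f degC^2\n",
              x$noise$var_day1, x$noise$var_day2, x$noise$var_night))
  invisible(x)
}

#' Noiseless model mean
#'
#' The expectation of an observation at time `t`: circadian component plus
#' linear trend.
#'
#' @param t Time in hours since phase start; vectorised, non-negative.
#' @param params A [full_model_params()] object.
#' @return Expected temperature, degrees Celsius.
#' @export
model_mean <- function(t, params) {
  stopifnot(inherits(params, "full_model_params"))
  circadian_component(t, params$vdp) + trend_at(t, params$trend)
}
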