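# Synthetic telemetry generator: study design, simulated temperature
# series under the observation model, a study-scale orchestrator with
# realistic default parameters, and a Runge-Kutta integrator of the exact
# van der Pol equation used as a validation oracle.

#' Study design of a three-phase telemetry experiment
#'
#' Describes the layout of an ovariectomized-rat style telemetry study:
#' ordered experimental phases with durations, the sampling cadence, the
#' light schedule, the daily variance-regime schedule and the group
#' assignment. Defaults emulate a three-phase protocol: a 6-day estrogen
#' reference phase (P1), a 6-day vehicle washout phase (P2) and a 10-day
#' treatment phase (P3), sampled every 3 minutes, with lights on
#' 06:00-18:00 and two treatment groups of 10 animals each.
#'
#' @param phases Named numeric vector of phase durations in days, in
#'   experimental order.
#' @param delta_t_min Sampling interval in minutes; must divide 24 hours
#'   evenly.
#' @param lights_on,lights_off Clock hours of the light period.
#' @param schedule A [variance_schedule()].
#' @param groups Named character vector mapping animal id to group label.
#' @param start_clock Clock hour at which each phase's recording starts
#'   (default 06:00, the start of the husbandry day).
#' @return An object of class `"study_design"`.
#' @export
study_design <- function(phases = c(P1 = 6, P2 = 6, P3 = 10),
                         delta_t_min = 3,
                         lights_on = 6, lights_off = 18,
                         schedule = variance_schedule(),
                         groups = default_groups(),
                         start_clock = 6) {
  stopifnot(is.numeric(phases), length(phases) >= 1L, !is.null(names(phases)))
  if (any(phases <= 0)) stop("phase durations must be positive (days)")
  if (abs((24 * 60) %% delta_t_min) > 1e-9)
    stop("'delta_t_min' must divide 24 hours evenly")
  stopifnot(inherits(schedule, "variance_schedule"),
            is.character(groups), !is.null(names(groups)))
  structure(list(phases = phases, delta_t_min = delta_t_min,
                 lights_on = lights_on, lights_off = lights_off,
                 schedule = schedule, groups = groups,
                 start_clock = start_clock),
            class = "study_design")
}

#' Default group assignment: 10 reference (E2) and 10 test (Tibolone)
#' animals
#'
#' @return Named character vector mapping animal ids `R01..R20` to group
#'   labels.
#' @export
default_groups <- function() {
  ids <- sprintf("R%02d", 1:20)
  stats::setNames(rep(c("E2", "Tibolone"), each = 10), ids)
}

#' Samples per day implied by a design's cadence
#' @param design A [study_design()].
#' @return Integer count (480 at the default 3-minute cadence).
#' @export
samples_per_day <- function(design) as.integer(round(24 * 60 / design$delta_t_min))

#' Telemetry temperature series for one animal in one phase
#'
#' @param time_h Hours since phase start; strictly increasing, nominally
#'   uniformly spaced (non-uniform gaps, e.g. from dropped records, are
#'   reported with a warning).
#' @param temperature Temperatures in degrees Celsius, same length.
#' @param animal_id,group,phase Metadata labels.
#' @param start_clock Clock hour of the first sample.
#' @param truth Optional [full_model_params()] ground truth (simulation
#'   only).
#' @return An object of class `"temperature_series"`.
#' @export
temperature_series <- function(time_h, temperature, animal_id = "A1",
                               group = NA_character_, phase = "P1",
                               start_clock = 6, truth = NULL) {
  stopifnot(is.numeric(time_h), is.numeric(temperature),
            length(time_h) == length(temperature), length(time_h) >= 2L)
  dt <- diff(time_h)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  if (max(dt) - min(dt) > 1e-8)
    warning("non-uniform sampling: ", sum(dt - min(dt) > 1e-8),
            " gap(s) in the timestamp grid")
  if (anyNA(temperature)) stop("temperature series must not contain missing values")
  structure(list(time_h = as.numeric(time_h),
                 temperature = as.numeric(temperature),
                 animal_id = animal_id, group = group, phase = phase,
                 start_clock = start_clock, delta_t_h = stats::median(dt),
                 truth = truth),
            class = "temperature_series")
}

#' @export
print.temperature_series <- function(x, ...) {
  cat(sprintf("temperature series: animal %s, group %s, phase %s\n",
              x$animal_id, x$group, x$phase))
  cat(sprintf("  %d samples every %.1f min over %.1f days, start %02.0f:00\n",
              length(x$time_h), x$delta_t_h * 60,
              diff(range(x$time_h)) / 24, x$start_clock))
  cat(sprintf("  temperature range [%.2f, %.2f] degC\n",
              min(x$temperature), max(x$temperature)))
  invisible(x)
}

#' @export
as.data.frame.temperature_series <- function(x, ...) {
  data.frame(animal_id = x$animal_id, group = x$group, phase = x$phase,
             time_h = x$time_h,
             clock_h = (x$start_clock + x$time_h) %% 24,
             temperature_c = x$temperature)
}

#' Clock time of each sample in a series
#' @param series A [temperature_series()].
#' @return Clock hours in `[0, 24)`.
#' @export
clock_time <- function(series) (series$start_clock + series$time_h) %% 24

#' Simulate one phase of telemetry under the observation model
#'
#' Draws `y_n = x(n*dt) + c(n*dt) + e_n` on the design's sampling grid,
#' with `e_n` independent normal and a variance chosen by the noise regime
#' of the sample's clock time.
#'
#' @param params A [full_model_params()] truth.
#' @param design A [study_design()].
#' @param phase Phase label, one of `names(design$phases)`.
#' @param seed Optional integer seed for reproducibility.
#' @param animal_id,group Metadata labels attached to the series.
#' @return A [temperature_series()] with the ground truth attached.
#' @export
#' @examples
#' truth <- full_model_params(
#'   vdp_params(0.5, 3, 0.4), trend_params(30), noise_params(10, 3.5, 9.8))
#' s <- simulate_phase(truth, study_design(), "P1", seed = 1)
#' length(s$temperature)  # 6 days x 480 samples
simulate_phase <- function(params, design, phase, seed = NULL,
                           animal_id = "A1", group = NA_character_) {
  stopifnot(inherits(params, "full_model_params"),
            inherits(design, "study_design"))
  if (!phase %in% names(design$phases))
    stop("unknown phase '", phase, "'; design has: ",
         paste(names(design$phases), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(design$phases[[phase]] * samples_per_day(design))
  dt_h <- design$delta_t_min / 60
  t <- (seq_len(n) - 1L) * dt_h
  regime <- regime_of((design$start_clock + t) %% 24, design$schedule)
  sd <- sqrt(regime_variance(regime, params$noise))
  y <- model_mean(t, params) + stats::rnorm(n, 0, sd)
  temperature_series(t, y, animal_id = animal_id, group = group,
                     phase = phase, start_clock = design$start_clock,
                     truth = params)
}

#' Simulate a full multi-animal, multi-phase study
#'
#' One series per (animal, phase) cell of the parameter table, with
#' per-series seeds derived deterministically from the master seed.
#'
#' @param param_table A data frame as produced by [default_scenario()]:
#'   one row per (animal, phase) with columns `animal_id`, `group`,
#'   `phase`, `a0`, `gamma`, `epsilon`, `psi`, `tau`, `c0`, `c1`,
#'   `var_day1`, `var_day2`, `var_night`.
#' @param design A [study_design()]; every (animal, phase) combination of
#'   the design must be covered by the table.
#' @param seed Integer master seed.
#' @return A list of [temperature_series()], named `<animal>_<phase>`.
#' @export
simulate_study <- function(param_table, design = study_design(), seed = 1L) {
  stopifnot(is.data.frame(param_table))
  need <- expand.grid(animal_id = names(design$groups),
                      phase = names(design$phases),
                      stringsAsFactors = FALSE)
  have <- paste(param_table$animal_id, param_table$phase)
  miss <- !(paste(need$animal_id, need$phase) %in% have)
  if (any(miss))
    stop("parameter table missing cells: ",
         paste(paste0(need$animal_id[miss], "/", need$phase[miss]),
               collapse = ", "))
  set.seed(seed)
  series_seeds <- sample.int(.Machine$integer.max - 1L, nrow(param_table))
  out <- vector("list", nrow(param_table))
  for (i in seq_len(nrow(param_table))) {
    row <- param_table[i, ]
    truth <- full_model_params(
      vdp_params(row$a0, row$gamma, row$epsilon, row$psi, row$tau),
      trend_params(row$c0, row$c1),
      noise_params(row$var_day1, row$var_day2, row$var_night))
    out[[i]] <- simulate_phase(truth, design, row$phase,
                               seed = series_seeds[i],
                               animal_id = row$animal_id, group = row$group)
  }
  names(out) <- paste(param_table$animal_id, param_table$phase, sep = "_")
  out
}

# group-level central values and between-animal spreads used by
# default_scenario(); one row per (group, phase)
scenario_central <- function() {
  df <- read.table(header = TRUE, text = "
group    phase a0   a0_sd gamma gamma_sd eps  eps_sd psi  psi_sd c0    c0_sd c1e4  c1e4_sd v1    v1_sd v2   v2_sd v3    v3_sd
E2       P1    0.65 0.32  3.97  1.48     0.52 0.26   0.24 0.19   29.53 1.68  0.31  1.99    9.87  3.69  4.06 1.28  10.39 2.76
E2       P2    2.48 0.98  1.58  0.55     0.29 0.25   0.40 0.34   30.35 1.12  1.37  1.39    9.56  3.25  4.91 3.55  11.17 2.40
E2       P3    1.43 0.61  2.70  1.00     0.31 0.26   0.16 0.36   30.71 0.74 -1.46  0.62   10.22  3.71  3.55 0.90   9.75 2.07
Tibolone P1    0.57 0.21  3.55  0.75     0.56 0.34   0.25 0.28   30.02 1.01  1.14  2.85    9.83  2.78  5.25 1.79  15.07 5.24
Tibolone P2    3.10 1.37  1.61  0.55     0.36 0.34   0.34 0.37   30.23 1.86  1.53  2.58   10.78  2.51  5.85 1.33  11.97 2.74
Tibolone P3    1.45 0.67  3.29  0.99     0.20 0.00   0.05 0.21   30.86 1.28 -3.15  1.15   14.77  3.50  4.57 1.34  11.28 2.68
")
  # printed slopes are per 3-minute sample; convert to degC per hour
  df$c1 <- df$c1e4 * 1e-4 * 20
  df$c1_sd <- df$c1e4_sd * 1e-4 * 20
  df
}

#' Default simulation scenario: per-animal truths around published-scale
#' group means
#'
#' Generates a per-animal, per-phase parameter table for the default
#' 2-group x 10-animal x 3-phase study. Each animal's parameters are
#' independent normal draws around group-by-phase central values typical
#' of fitted tail-skin temperature rhythms (reference group limit-cycle
#' amplitude about 3.97 degC in P1, collapsing to 1.58 degC in the vehicle
#' phase and restored to 2.70 degC under treatment; baselines near 30
#' degC; regime variances of 3.5-15 degC^2), with the stated between-animal
#' spreads used as standard deviations. Draws are clipped to valid ranges
#' (`epsilon` to `[0.2, 1]`, amplitudes and variances away from zero).
#'
#' @param design A [study_design()] providing animals and phases.
#' @param seed Integer seed for the parameter draws.
#' @return Parameter table suitable for [simulate_study()].
#' @export
default_scenario <- function(design = study_design(), seed = 1L) {
  set.seed(seed)
  cen <- scenario_central()
  rows <- list()
  for (id in names(design$groups)) {
    g <- design$groups[[id]]
    for (ph in names(design$phases)) {
      ce <- cen[cen$group == g & cen$phase == ph, ]
      if (nrow(ce) != 1L)
        stop("no scenario central values for group ", g, ", phase ", ph)
      draw <- function(m, s) stats::rnorm(1L, m, s)
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = id, group = g, phase = ph,
        a0      = max(0.1, draw(ce$a0, ce$a0_sd)),
        gamma   = max(0.1, draw(ce$gamma, ce$gamma_sd)),
        epsilon = min(1, max(0.2, draw(ce$eps, ce$eps_sd))),
        psi     = min(pi, max(-pi, draw(ce$psi, ce$psi_sd))),
        tau     = 24,
        c0      = max(20, draw(ce$c0, ce$c0_sd)),
        c1      = draw(ce$c1, ce$c1_sd),
        var_day1 = max(0.5, draw(ce$v1, ce$v1_sd)),
        var_day2 = max(0.5, draw(ce$v2, ce$v2_sd)),
        var_night = max(0.5, draw(ce$v3, ce$v3_sd)))
    }
  }
  do.call(rbind, rows)
}

#' State of the perturbation solution
#'
#' Position and velocity of the circadian component at time `t`, with the
#' velocity obtained by differentiating the perturbation solution (using
#' the amplitude equation for `da/dt`). Used to start the exact-equation
#' integrator on the perturbation orbit.
#'
#' @param params A [vdp_params()] object.
#' @param t Time in hours (default 0).
#' @return Numeric vector `c(x, xdot)` in degC and degC per hour.
#' @export
perturbation_state <- function(params, t = 0) {
  om <- omega_of(params)
  eps <- params$epsilon; gam <- params$gamma; psi <- params$psi
  a <- amplitude_at(t, params)
  adot <- eps * a * om / 2 * (1 - a^2 / gam^2)
  ph1 <- om * t + psi
  ph3 <- 3 * om * t + 3 * psi
  x <- a * cos(ph1) - eps * a^3 / (8 * gam^2) * sin(ph3)
  xdot <- adot * cos(ph1) - a * om * sin(ph1) -
    eps / (8 * gam^2) * (3 * a^2 * adot * sin(ph3) + 3 * om * a^3 * cos(ph3))
  c(x = unname(x), xdot = unname(xdot))
}

#' Integrate the exact van der Pol equation (validation oracle)
#'
#' Fixed-step fourth-order Runge-Kutta integration of
#' `x'' + epsilon*omega*(4*x^2/gamma^2 - 1)*x' + omega^2*x = 0`, the
#' nonlinear oscillator whose stable limit cycle (for `epsilon > 0`) has
#' amplitude close to `gamma`. This is the reference trajectory against
#' which the closed-form perturbation solution is validated; the
#' observation model itself is always built on the perturbation solution.
#'
#' @param params A [vdp_params()] object (`a0` is ignored; the initial
#'   state fixes the orbit).
#' @param initial_state Numeric `c(x, xdot)` at time 0.
#' @param duration Integration horizon in hours.
#' @param step Fixed step size in hours (default 0.02; keep at or below
#'   0.05 for stability at circadian frequencies).
#' @return A data frame with columns `time`, `x`, `xdot`.
#' @export
#' @examples
#' p <- vdp_params(a0 = 2, gamma = 2, epsilon = 0, psi = 0)
#' tr <- integrate_vdp_ode(p, c(2, 0), duration = 48)
#' max(abs(tr$x - 2 * cos(2 * pi / 24 * tr$time)))  # harmonic limit
integrate_vdp_ode <- function(params, initial_state, duration,
                              step = 0.02) {
  stopifnot(inherits(params, "vdp_params"), is.numeric(initial_state),
            length(initial_state) == 2L)
  if (duration <= 0) stop("'duration' must be positive (hours)")
  if (step <= 0 || step > duration) stop("invalid 'step'")
  om <- omega_of(params)
  eps <- params$epsilon; gam <- params$gamma
  deriv <- function(t, state, parms) {
    list(c(state[2L],
           -eps * om * (4 * state[1L]^2 / gam^2 - 1) * state[2L] -
             om^2 * state[1L]))
  }
  times <- seq(0, duration, by = step)
  initial_state <- unname(initial_state)
  out <- deSolve::rk4(c(x = initial_state[1L], xdot = initial_state[2L]),
                      times, deriv, parms = NULL)
  data.frame(time = out[, "time"], x = out[, "x"], xdot = out[, "xdot"])
}
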