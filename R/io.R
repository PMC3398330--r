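# File formats and pipeline plumbing: long-format telemetry CSV in and
# out, fit summaries, JSON reports, and the high-level simulate/fit/
# compare pipeline behind the command-line interface.

#' Read telemetry series from a long-format CSV
#'
#' Expects columns `animal_id`, `group`, `phase`, `timestamp`,
#' `temperature_c`. Timestamps are either ISO 8601 date-times (clock time
#' is used for noise-regime assignment) or numeric minutes since phase
#' start (then `start_clock` supplies the clock time of the first
#' sample). Rows with missing temperatures are dropped with a message;
#' rows are sorted by timestamp within each (animal, phase).
#'
#' @param path CSV file path.
#' @param start_clock Clock hour of the first sample, used only for
#'   numeric timestamps.
#' @return A named list of [temperature_series()], one per
#'   (animal, phase).
#' @export
read_series <- function(path, start_clock = 6) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "phase", "timestamp", "temperature_c")
  missing_col <- setdiff(need, names(df))
  if (length(missing_col))
    stop("missing required column(s): ", paste(missing_col, collapse = ", "))
  na_temp <- is.na(df$temperature_c)
  if (any(na_temp)) {
    message("dropping ", sum(na_temp), " row(s) with missing temperature")
    df <- df[!na_temp, ]
  }
  iso <- grepl("[T ]", as.character(df$timestamp[1L]))
  out <- list()
  for (key in unique(paste(df$animal_id, df$phase, sep = "_"))) {
    sub <- df[paste(df$animal_id, df$phase, sep = "_") == key, ]
    if (iso) {
      ts <- as.POSIXct(sub$timestamp, tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
      if (anyNA(ts)) stop("unparseable timestamp(s) in series ", key)
      o <- order(ts)
      ts <- ts[o]; sub <- sub[o, ]
      if (anyDuplicated(ts))
        stop("duplicate (animal, phase, timestamp) rows in series ", key)
      t_h <- as.numeric(difftime(ts, ts[1L], units = "hours"))
      sc <- as.numeric(difftime(ts[1L], trunc(ts[1L], "days"),
                                units = "hours"))
    } else {
      tm <- suppressWarnings(as.numeric(sub$timestamp))
      if (anyNA(tm)) stop("unparseable timestamp(s) in series ", key)
      o <- order(tm)
      tm <- tm[o]; sub <- sub[o, ]
      if (anyDuplicated(tm))
        stop("duplicate (animal, phase, timestamp) rows in series ", key)
      t_h <- (tm - tm[1L]) / 60
      sc <- start_clock
    }
    out[[key]] <- temperature_series(t_h, sub$temperature_c,
                                     animal_id = sub$animal_id[1L],
                                     group = sub$group[1L],
                                     phase = sub$phase[1L],
                                     start_clock = sc)
  }
  out
}

#' Write telemetry series to a long-format CSV
#'
#' Inverse of [read_series()]: ISO 8601 timestamps are synthesised from an
#' origin date plus each series' start clock time, and temperatures are
#' written with 4 decimal places.
#'
#' @param series_list A list of [temperature_series()].
#' @param path Output CSV path.
#' @param origin_date Calendar date of each phase's first day.
#' @return The path, invisibly.
#' @export
write_series <- function(series_list, path, origin_date = "2000-01-01") {
  if (inherits(series_list, "temperature_series"))
    series_list <- list(series_list)
  rows <- lapply(series_list, function(s) {
    t0 <- as.POSIXct(paste0(origin_date, " 00:00:00"), tz = "UTC") +
      s$start_clock * 3600
    data.frame(animal_id = s$animal_id, group = s$group, phase = s$phase,
               timestamp = format(t0 + round(s$time_h * 3600),
                                  "%Y-%m-%dT%H:%M:%S"),
               temperature_c = sprintf("%.4f", s$temperature))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Flat summary table of phase fits
#'
#' One row per (animal, phase) with the oscillator estimates, the
#' amplitude at phase end, trend and variance estimates, NLL and AIC.
#'
#' @param fits A list of `phase_fit` objects.
#' @return A data frame.
#' @export
fit_summary <- function(fits) {
  if (inherits(fits, "phase_fit")) fits <- list(fits)
  do.call(rbind, lapply(fits, function(f) {
    v <- f$params$vdp; tr <- f$params$trend; no <- f$params$noise
    data.frame(animal_id = f$animal_id, group = f$group, phase = f$phase,
               a0 = v$a0, epsilon = v$epsilon, psi = v$psi,
               gamma = v$gamma, a_at_T = f$a_at_T,
               c0 = tr$c0, c1 = tr$c1,
               var_day1 = no$var_day1, var_day2 = no$var_day2,
               var_night = no$var_night,
               negloglik = f$negloglik, aic = f$aic,
               converged = f$convergence)
  }))
}

#' Write a phase fit (or list of fits) as JSON
#'
#' @param fits A `phase_fit` or list of them.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fits, path) {
  if (inherits(fits, "phase_fit")) fits <- list(fits)
  payload <- lapply(fits, function(f) {
    list(animal_id = f$animal_id, group = f$group, phase = f$phase,
         estimates = list(
           a0 = f$params$vdp$a0, gamma = f$params$vdp$gamma,
           epsilon = f$params$vdp$epsilon, psi = f$params$vdp$psi,
           tau = f$params$vdp$tau,
           c0 = f$params$trend$c0, c1 = f$params$trend$c1,
           var_day1 = f$params$noise$var_day1,
           var_day2 = f$params$noise$var_day2,
           var_night = f$params$noise$var_night),
         a_at_T = f$a_at_T, T_end = f$T_end,
         negloglik = f$negloglik, aic = f$aic,
         bounds = f$bounds, init = as.list(f$init),
         converged = f$convergence, n = f$n,
         time_unit = f$time_unit)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Group comparison report on an amplitude table
#'
#' Runs the full inference battery: per-group mean P2 - P3 pairwise
#' differences with one-sided upper bootstrap confidence intervals, and
#' the ratio-based non-inferiority test between the reference and test
#' groups.
#'
#' @param table An [amplitude_table()] data frame.
#' @param ref_group,test_group Group labels of the reference and test
#'   treatment.
#' @param B Bootstrap replicates.
#' @param alpha Significance level.
#' @param margin Non-inferiority margin on the ratio scale.
#' @param seed Integer seed governing all bootstrap draws.
#' @return A list with one `comparison_result` per group contrast
#'   (`differences`) and the `ratio_test`.
#' @export
comparison_report <- function(table, ref_group = "E2",
                              test_group = "Tibolone", B = 1000L,
                              alpha = 0.05, margin = 0.2, seed = 1L) {
  groups <- unique(table$group)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(groups) + 1L)
  diffs <- stats::setNames(lapply(seq_along(groups), function(i) {
    bootstrap_mean_ci(pairwise_differences(table, groups[i]),
                      B = B, alpha = alpha, side = "upper",
                      seed = seeds[i])
  }), groups)
  rt <- ratio_noninferiority_test(
    reconstruction_ratios(table, ref_group),
    reconstruction_ratios(table, test_group),
    margin = margin, B = B, alpha = alpha,
    seed = seeds[length(seeds)])
  list(differences = diffs, ratio_test = rt,
       settings = list(B = B, alpha = alpha, margin = margin, seed = seed,
                       ref_group = ref_group, test_group = test_group))
}

#' Render a comparison report as text
#'
#' @param report Output of [comparison_report()].
#' @return Character vector of report lines.
#' @export
format_comparison_report <- function(report) {
  lines <- c("Mean differences between vehicle and treatment phase (P2 - P3)",
             sprintf("  %-10s estimate %8.4f   CI (-Inf, %8.4f]",
                     names(report$differences),
                     vapply(report$differences, function(x) x$estimate, 0),
                     vapply(report$differences, function(x) x$ci[["upper"]], 0)),
             "",
             "Amplitude reconstruction (Q = gamma_P3 / gamma_P1), difference of group medians",
             sprintf("  %s - %s: estimate %.4f   CI (-Inf, %.4f]   p_%.1f = %.4f   %s",
                     report$settings$ref_group, report$settings$test_group,
                     report$ratio_test$estimate,
                     report$ratio_test$ci[["upper"]],
                     report$ratio_test$margin, report$ratio_test$p_value,
                     if (report$ratio_test$reject)
                       "similar recovery (H0 rejected)"
                     else "similar recovery not established"))
  lines
}

#' Write a comparison report as JSON
#'
#' @param report Output of [comparison_report()].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  payload <- list(
    differences = lapply(report$differences, function(x)
      list(estimate = x$estimate, ci_upper = x$ci[["upper"]],
           B = x$B, alpha = x$alpha, n = x$n)),
    ratio_test = list(estimate = report$ratio_test$estimate,
                      ci_upper = report$ratio_test$ci[["upper"]],
                      p_value = report$ratio_test$p_value,
                      margin = report$ratio_test$margin,
                      reject = report$ratio_test$reject,
                      B = report$ratio_test$B,
                      alpha = report$ratio_test$alpha),
    settings = report$settings)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full simulate-fit-compare pipeline on the default scenario
#'
#' Convenience wrapper: draws per-animal truths with [default_scenario()],
#' simulates every series, fits each one with [fit_phase()], assembles the
#' amplitude table and returns the [comparison_report()].
#'
#' @param seed Master seed for scenario, simulation and bootstrap.
#' @param design A [study_design()].
#' @param config A [fit_config()].
#' @param B,alpha,margin Inference settings.
#' @return List with `param_table`, `fits` (summary data frame), `table`
#'   (amplitude table) and `report`.
#' @export
run_default_pipeline <- function(seed = 1L, design = study_design(),
                                 config = fit_config(), B = 1000L,
                                 alpha = 0.05, margin = 0.2) {
  param_table <- default_scenario(design, seed = seed)
  series <- simulate_study(param_table, design, seed = seed + 1L)
  fits <- lapply(series, fit_phase, config = config)
  table <- amplitude_table(fits, phases = names(design$phases))
  report <- comparison_report(table, B = B, alpha = alpha, margin = margin,
                              seed = seed + 2L)
  list(param_table = param_table, fits = fit_summary(fits), table = table,
       report = report)
}
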