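# Group-level treatment-effect statistics on fitted limit-cycle
# amplitudes: within-animal phase differences with percentile-bootstrap
# confidence intervals for the mean, amplitude-reconstruction ratios, and
# a one-sided bootstrap non-inferiority test on the difference of group
# medians.

#' Assemble the per-animal limit-cycle amplitude table
#'
#' One row per animal with the fitted limit-cycle amplitude `gamma` of
#' each phase, the quantity carrying the treatment-effect endpoint.
#'
#' @param fits A list of `phase_fit` objects (from [fit_phase()]) covering
#'   every (animal, phase) combination.
#' @param phases Phase labels expected per animal.
#' @return A data frame with columns `animal_id`, `group` and
#'   `gamma_<phase>` for each phase.
#' @export
amplitude_table <- function(fits, phases = c("P1", "P2", "P3")) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  df <- do.call(rbind, lapply(fits, function(f) {
    stopifnot(inherits(f, "phase_fit"))
    data.frame(animal_id = f$animal_id, group = f$group, phase = f$phase,
               gamma = f$params$vdp$gamma)
  }))
  wide <- stats::reshape(df, idvar = c("animal_id", "group"),
                         timevar = "phase", direction = "wide")
  names(wide) <- sub("^gamma\\.", "gamma_", names(wide))
  need <- paste0("gamma_", phases)
  missing_col <- setdiff(need, names(wide))
  if (length(missing_col))
    stop("no fits for phase(s): ",
         paste(sub("gamma_", "", missing_col), collapse = ", "))
  rownames(wide) <- NULL
  wide[, c("animal_id", "group", need)]
}

#' Within-animal limit-cycle amplitude differences between two phases
#'
#' Per-animal `gamma_P2 - gamma_P3` (by default): negative values indicate
#' amplitude restoration during treatment.
#'
#' @param table An [amplitude_table()] data frame.
#' @param group Group label to restrict to (`NULL` keeps all animals).
#' @param from,to Phase labels of the difference `from - to`.
#' @return Named numeric vector of differences, one per animal.
#' @export
pairwise_differences <- function(table, group = NULL,
                                 from = "P2", to = "P3") {
  stopifnot(is.data.frame(table))
  if (!is.null(group)) table <- table[table$group == group, ]
  if (nrow(table) == 0L) stop("no animals in group '", group, "'")
  cf <- paste0("gamma_", from); ct <- paste0("gamma_", to)
  stopifnot(cf %in% names(table), ct %in% names(table))
  bad <- !is.finite(table[[cf]]) | !is.finite(table[[ct]])
  if (any(bad))
    stop("missing phase estimate for animal(s): ",
         paste(table$animal_id[bad], collapse = ", "))
  stats::setNames(table[[cf]] - table[[ct]], table$animal_id)
}

#' Percentile-bootstrap confidence interval for a mean
#'
#' Resamples the values with replacement `B` times and forms a one-sided
#' percentile interval for the mean: side `"upper"` reports
#' `(-Inf, q_{1-alpha}]` of the bootstrap means, side `"lower"` reports
#' `[q_alpha, Inf)`.
#'
#' @param values Numeric sample (length >= 2).
#' @param B Number of bootstrap replicates (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param side `"upper"` or `"lower"`.
#' @param seed Optional integer seed.
#' @return An object of class `"comparison_result"` with the sample mean
#'   as `estimate`, the interval, `B`, `alpha` and the seed.
#' @export
bootstrap_mean_ci <- function(values, B = 1000L, alpha = 0.05,
                              side = c("upper", "lower"), seed = NULL) {
  stopifnot(is.numeric(values), length(values) >= 2L, all(is.finite(values)))
  if (B < 1L) stop("'B' must be at least 1")
  if (!(alpha > 0 && alpha < 1)) stop("'alpha' must be in (0, 1)")
  side <- match.arg(side)
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  boot <- colMeans(matrix(sample(values, n * B, replace = TRUE), nrow = n))
  ci <- if (side == "upper")
    c(lower = -Inf, upper = unname(stats::quantile(boot, 1 - alpha)))
  else
    c(lower = unname(stats::quantile(boot, alpha)), upper = Inf)
  structure(list(estimate = mean(values), ci = ci, p_value = NA_real_,
                 B = as.integer(B), alpha = alpha, side = side,
                 seed = seed, margin = NA_real_, n = n,
                 statistic = "bootstrap mean"),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s (n = %s, B = %d):\n", x$statistic,
              paste(x$n, collapse = " + "), x$B))
  cat(sprintf("  estimate %.4f, %d%% CI (%s, %s]\n",
              x$estimate, round(100 * (1 - x$alpha)),
              format(x$ci[["lower"]], digits = 4),
              format(x$ci[["upper"]], digits = 4)))
  if (is.finite(x$p_value))
    cat(sprintf("  p = %.4f at non-inferiority margin %.2f\n",
                x$p_value, x$margin))
  invisible(x)
}

#' Amplitude-reconstruction ratios
#'
#' Per-animal ratio `Q = gamma_P3 / gamma_P1` of the treatment-phase
#' limit-cycle amplitude to the reference-phase amplitude; `Q` near 1
#' means the treatment restored the pre-ovariectomy reference amplitude.
#'
#' @param table An [amplitude_table()] data frame.
#' @param group Group label to restrict to (`NULL` keeps all animals).
#' @param num,den Phase labels of numerator and denominator.
#' @return Named numeric vector of positive ratios.
#' @export
reconstruction_ratios <- function(table, group = NULL,
                                  num = "P3", den = "P1") {
  stopifnot(is.data.frame(table))
  if (!is.null(group)) table <- table[table$group == group, ]
  if (nrow(table) == 0L) stop("no animals in group '", group, "'")
  cn <- paste0("gamma_", num); cd <- paste0("gamma_", den)
  stopifnot(cn %in% names(table), cd %in% names(table))
  bad <- !is.finite(table[[cd]]) | table[[cd]] <= 0
  if (any(bad))
    stop("non-positive reference amplitude for animal(s): ",
         paste(table$animal_id[bad], collapse = ", "))
  stats::setNames(table[[cn]] / table[[cd]], table$animal_id)
}

#' One-sided bootstrap non-inferiority test on the difference of medians
#'
#' Tests `H0: median(q_ref) - median(q_test) >= margin` against
#' `H1: median(q_ref) - median(q_test) < margin` for two independent
#' samples of reconstruction ratios. Each group is resampled independently
#' `B` times; the test reports the sample difference of medians, the
#' one-sided `(1-alpha)` percentile interval `(-Inf, upper]` of the
#' bootstrap differences, and the p-value `P*(d* >= margin)`. `H0` is
#' rejected (similar recovery concluded) when the interval's upper
#' endpoint lies below the margin.
#'
#' @param q_ref Ratios of the reference group.
#' @param q_test Ratios of the test group.
#' @param margin Non-inferiority margin on the ratio scale (default 0.2).
#' @param B Bootstrap replicates (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Optional integer seed.
#' @return A `comparison_result` with `estimate`, `ci`, `p_value`,
#'   `margin` and a `reject` flag.
#' @export
ratio_noninferiority_test <- function(q_ref, q_test, margin = 0.2,
                                      B = 1000L, alpha = 0.05,
                                      seed = NULL) {
  stopifnot(is.numeric(q_ref), is.numeric(q_test),
            length(q_ref) >= 1L, length(q_test) >= 1L,
            all(is.finite(q_ref)), all(is.finite(q_test)))
  if (B < 1L) stop("'B' must be at least 1")
  if (!(alpha > 0 && alpha < 1)) stop("'alpha' must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n1 <- length(q_ref); n2 <- length(q_test)
  m_ref <- boot_medians(q_ref, B)
  m_test <- boot_medians(q_test, B)
  d <- m_ref - m_test
  degenerate <- stats::sd(c(q_ref, q_test)) == 0
  if (degenerate)
    warning("degenerate samples: all ratios identical; p-value trivial")
  upper <- unname(stats::quantile(d, 1 - alpha))
  p <- mean(d >= margin)
  res <- structure(list(estimate = stats::median(q_ref) - stats::median(q_test),
                        ci = c(lower = -Inf, upper = upper),
                        p_value = p, B = as.integer(B), alpha = alpha,
                        side = "upper", seed = seed, margin = margin,
                        n = c(n1, n2), reject = upper < margin,
                        statistic = "bootstrap difference of group medians"),
                   class = "comparison_result")
  res
}

# B bootstrap medians of one sample, vectorised over a resample matrix
boot_medians <- function(x, B) {
  n <- length(x)
  m <- matrix(sample(x, n * B, replace = TRUE), nrow = n)
  m <- apply(m, 2L, sort)
  if (n %% 2L == 1L) m[(n + 1L) %/% 2L, ]
  else (m[n %/% 2L, ] + m[n %/% 2L + 1L, ]) / 2
}
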