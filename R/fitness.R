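#' Relative fitness from the slope of the log count ratio
#'
#' Relative fitness of competitor a versus competitor b is the ordinary
#' least-squares slope of `ln(count_a / count_b)` against generation, in
#' per-generation units. Timepoints at or after the first zero count are
#' excluded: a zero count signals fixation or loss, which is reported as a
#' boundary outcome rather than extrapolated with pseudocounts.
#'
#' @param tc A [competition_timecourse()].
#' @return An object of class `fitness_estimate`: a list with `s_hat`,
#'   `stderr` (`NA` with exactly two usable timepoints), `n_timepoints`,
#'   `orientation` (`"a_vs_b"`), and `boundary` (`NULL`, or a list with
#'   `outcome` `"fixed"`/`"lost"` and `generation` when a count hit zero).
#' @export
#'
#' @examples
#' tp <- data.frame(generation = c(0, 10), count_a = c(1000, 1221),
#'                  count_b = c(1000, 1000), sample_size = c(2000, 2221))
#' log_ratio_slope(competition_timecourse("a", "b", tp))$s_hat  # ~0.0200
log_ratio_slope <- function(tc) {
  stopifnot(inherits(tc, "competition_timecourse"))
  zero <- tc$count_a == 0 | tc$count_b == 0
  boundary <- NULL
  usable <- tc
  if (any(zero)) {
    first <- which(zero)[1L]
    boundary <- list(
      outcome = if (tc$count_b[first] == 0) "fixed" else "lost",
      generation = tc$generation[first])
    usable <- tc[seq_len(first - 1L), , drop = FALSE]
  }
  if (nrow(usable) < 2L)
    stop("fitness undefined: fewer than 2 timepoints with both counts > 0 (",
         if (is.null(boundary)) "too short" else
           paste0("competitor ", boundary$outcome, " by generation ", boundary$generation),
         ")")
  lr <- log(usable$count_a / usable$count_b)
  fit <- stats::lm(lr ~ usable$generation)
  s_hat <- unname(stats::coef(fit)[2L])
  # suppressWarnings: noise-free (deterministic-mode) courses fit perfectly
  stderr <- if (nrow(usable) > 2L)
    unname(suppressWarnings(summary(fit))$coefficients[2L, 2L]) else NA_real_
  structure(list(s_hat = s_hat, stderr = stderr,
                 n_timepoints = nrow(usable), orientation = "a_vs_b",
                 boundary = boundary),
            class = "fitness_estimate")
}

#' @export
print.fitness_estimate <- function(x, ...) {
  cat(sprintf("Relative fitness (a vs b): s = %.4f per generation%s, n = %d\n",
              x$s_hat,
              if (is.na(x$stderr)) "" else sprintf(" (SE %.4f)", x$stderr),
              x$n_timepoints))
  if (!is.null(x$boundary))
    cat(sprintf("  boundary: competitor a %s by generation %d\n",
                x$boundary$outcome, x$boundary$generation))
  invisible(x)
}

#' Per-interval fitness estimates
#'
#' Analyses each consecutive timepoint pair independently: the interval's
#' starting frequency is `count_a / sample_size` at its first timepoint and
#' its fitness is the change in `ln(count_a / count_b)` divided by the
#' generation span. Intervals touching a zero count are flagged (`excluded =
#' TRUE`) with `s_hat = NA`, not dropped silently.
#'
#' @param tc A [competition_timecourse()].
#' @return A data frame of class `interval_estimates` with columns `start`,
#'   `end`, `f0`, `s_hat`, `excluded`.
#' @export
interval_fitness <- function(tc) {
  stopifnot(inherits(tc, "competition_timecourse"))
  if (nrow(tc) < 2L) stop("at least 2 timepoints are required")
  i <- seq_len(nrow(tc) - 1L)
  lr <- log(tc$count_a / tc$count_b)
  out <- data.frame(
    start = tc$generation[i],
    end = tc$generation[i + 1L],
    f0 = tc$count_a[i] / tc$sample_size[i],
    s_hat = (lr[i + 1L] - lr[i]) / (tc$generation[i + 1L] - tc$generation[i]),
    excluded = (tc$count_a[i] == 0 | tc$count_b[i] == 0 |
                  tc$count_a[i + 1L] == 0 | tc$count_b[i + 1L] == 0))
  out$s_hat[out$excluded] <- NA_real_
  structure(out, class = c("interval_estimates", "data.frame"),
            competitor_a = attr(tc, "competitor_a"),
            competitor_b = attr(tc, "competitor_b"))
}

#' Detect frequency-dependent selection from interval estimates
#'
#' Regresses per-interval fitness on starting frequency by ordinary least
#' squares. The slope's two-sided t-test at `alpha` classifies the dependence
#' as `"positive"`, `"negative"`, or `"none"`. Under positive frequency
#' dependence the fitted zero crossing `-intercept / beta`, when it lies in
#' (0, 1), is reported as the unstable equilibrium frequency `f_star` of the
#' bistable system: started above it the focal competitor invades, below it
#' it is eliminated.
#'
#' @param intervals An `interval_estimates` data frame (rows from several
#'   competitions at different starting frequencies may be concatenated), or
#'   any data frame with columns `f0` and `s_hat`.
#' @param alpha Two-sided test level (default 0.01).
#' @return An object of class `freq_dependence`: list with `beta`,
#'   `intercept`, `p_value`, `classification`, `f_star` (`NA` unless
#'   positive with a crossing in (0, 1)), `alpha`, `n`.
#' @export
frequency_dependence <- function(intervals, alpha = 0.01) {
  df <- as.data.frame(intervals)
  if (!all(c("f0", "s_hat") %in% names(df)))
    stop("intervals must have columns f0 and s_hat")
  df <- df[!is.na(df$s_hat), , drop = FALSE]
  if (nrow(df) < 3L) stop("at least 3 usable intervals are required")
  if (length(unique(df$f0)) < 2L)
    stop("all starting frequencies identical: frequency dependence undefined")
  fit <- stats::lm(s_hat ~ f0, data = df)
  co <- suppressWarnings(summary(fit))$coefficients
  beta <- co["f0", "Estimate"]
  p <- co["f0", "Pr(>|t|)"]
  # a flat, exactly-fit response (all s_hat equal) has beta = 0 and an
  # undefined t-test; that is "no dependence", not an error
  classification <- if (!is.na(p) && p < alpha) {
    if (beta > 0) "positive" else "negative"
  } else "none"
  f_star <- NA_real_
  if (classification == "positive") {
    cross <- -co["(Intercept)", "Estimate"] / beta
    if (cross > 0 && cross < 1) f_star <- cross
  }
  structure(list(beta = beta, intercept = co["(Intercept)", "Estimate"],
                 p_value = p, classification = classification,
                 f_star = f_star, alpha = alpha, n = nrow(df)),
            class = "freq_dependence")
}

#' @export
print.freq_dependence <- function(x, ...) {
  cat(sprintf("Frequency dependence: %s (beta = %.4f, p = %.3g, n = %d)\n",
              x$classification, x$beta, x$p_value, x$n))
  if (!is.na(x$f_star))
    cat(sprintf("  unstable equilibrium f* = %.3f\n", x$f_star))
  invisible(x)
}
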