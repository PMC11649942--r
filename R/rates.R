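#' Regress ILD sensitivity on log pulse rate
#'
#' Ordinary least squares of one sensitivity measure (slope or JND) on
#' `log(pps)`, pooling all (subject, pulse-rate) points into a single
#' regression. Undefined values are excluded listwise with the exclusion
#' count reported. The logarithm's base defaults to 10 and only rescales the
#' slope; the R-squared and p-value are base-invariant.
#'
#' @param results A sensitivity tibble from [ild_sensitivity()] with points
#'   at two or more distinct pulse rates (at least 3 points overall).
#' @param measure `"slope"` (the psychometric slope at ILD = 0, %/dB) or
#'   `"jnd"` (dB).
#' @param log_base Base of the logarithm applied to `pps`.
#' @return An object of class `rate_regression`: list with `measure`,
#'   `log_base`, `slope` (measure units per log-unit of pps), `intercept`,
#'   `r_squared`, `p_value` (two-sided t-test of slope = 0), `n_points`,
#'   `df`, `n_excluded`, and the underlying `lm` fit.
#' @examples
#' sens <- tibble::tibble(
#'   subject = rep(c("a", "b"), each = 3), pps = rep(c(50, 900, 2400), 2),
#'   jnd_db = c(0.5, 1.2, 1.9, 0.7, 1.4, 2.1),
#'   slope_pct_per_db = c(30, 15, 9, 25, 13, 8)
#' )
#' glance(regress_log_rate(sens, "jnd"))
#' @export
regress_log_rate <- function(results, measure = c("slope", "jnd"),
                             log_base = 10) {
  measure <- match.arg(measure)
  stopifnot(is.data.frame(results), log_base > 0, log_base != 1)
  col <- if (measure == "slope") "slope_pct_per_db" else "jnd_db"
  if (!all(c("pps", col) %in% names(results))) {
    abort(sprintf("`results` needs columns `pps` and `%s`.", col))
  }
  d <- tibble(pps = results$pps, value = results[[col]])
  n_excluded <- sum(!is.finite(d$value))
  d <- d |> dplyr::filter(is.finite(.data$value))
  if (nrow(d) < 3) abort("Need at least 3 defined points for the regression.")
  if (length(unique(d$pps)) < 2) {
    abort("All pulse rates are identical; the regression on log(pps) is undefined.")
  }
  d$log_pps <- log(d$pps, base = log_base)
  fit <- lm(value ~ log_pps, data = d)
  sm <- summary(fit)
  r2 <- sm$r.squared
  pv <- sm$coefficients["log_pps", "Pr(>|t|)"]
  if (stats::var(d$value) < .Machine$double.eps) {
    # a constant response carries no rate dependence at all
    r2 <- 0
    pv <- 1
  }
  structure(
    list(
      measure = measure,
      log_base = log_base,
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = r2,
      p_value = pv,
      n_points = nrow(d),
      df = nrow(d) - 2L,
      n_excluded = n_excluded,
      lm = fit
    ),
    class = "rate_regression"
  )
}

#' @export
print.rate_regression <- function(x, ...) {
  cat(sprintf(
    "<rate_regression> %s ~ log%g(pps): slope %.4g, intercept %.4g, R^2 %.3f, p = %.4g (n = %d, df = %d, excluded %d)\n",
    x$measure, x$log_base, x$slope, x$intercept, x$r_squared, x$p_value,
    x$n_points, x$df, x$n_excluded
  ))
  invisible(x)
}

#' @export
tidy.rate_regression <- function(x, ...) {
  tibble(
    term = c("intercept", sprintf("log%g_pps", x$log_base)),
    estimate = c(x$intercept, x$slope)
  )
}

#' @export
glance.rate_regression <- function(x, ...) {
  tibble(
    measure = x$measure, slope = x$slope, intercept = x$intercept,
    r_squared = x$r_squared, p_value = x$p_value,
    n_points = x$n_points, df = x$df, n_excluded = x$n_excluded
  )
}

#' Mean sensitivity per pulse rate
#'
#' Arithmetic mean of each sensitivity measure across subjects at each pulse
#' rate, excluding undefined values with counts reported.
#'
#' @param results A sensitivity tibble from [ild_sensitivity()].
#' @return A long tibble: `pps`, `measure` (`"slope"`/`"jnd"`), `mean_value`,
#'   `n_used`, `n_excluded`.
#' @export
mean_by_rate <- function(results) {
  stopifnot(is.data.frame(results))
  results |>
    dplyr::select("pps", slope = "slope_pct_per_db", jnd = "jnd_db") |>
    tidyr::pivot_longer(c("slope", "jnd"), names_to = "measure",
                        values_to = "value") |>
    dplyr::group_by(.data$pps, .data$measure) |>
    dplyr::summarise(
      mean_value = mean(.data$value[is.finite(.data$value)]),
      n_used = sum(is.finite(.data$value)),
      n_excluded = sum(!is.finite(.data$value)),
      .groups = "drop"
    )
}
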