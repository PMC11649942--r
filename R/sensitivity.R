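#' Just noticeable difference (JND) of a fitted psychometric curve
#'
#' The ILD change required to raise the probability of a "right" response
#' from 50% to 75% on the spout-bias-corrected fitted curve (the vertical
#' offset `delta` is removed before inverting; the lapse term is retained by
#' default). For the probit model this has the closed form
#' `qnorm((0.75 - gamma/2) / (1 - gamma)) / |alpha|` — the ear bias `beta`
#' shifts the curve horizontally and cancels in the difference — and for the
#' bounded linear model it is `0.25 / |alpha|`. `|alpha|` keeps the JND
#' positive for left-preferring fits.
#'
#' The JND is undefined (returned as `NA` with reason attached) for the null
#' model, for `alpha = 0`, and for `gamma >= 0.5`, where the lapse-retained
#' curve never reaches 75%; no number is fabricated in those cases.
#'
#' @param fit An `ild_fit`.
#' @param lapse_corrected If `TRUE`, remove the lapse term as well as the
#'   spout bias before inverting (probit JND becomes `qnorm(0.75) / |alpha|`).
#'   Default `FALSE`.
#' @return JND in dB (`NA` if undefined, with attribute `reason`).
#' @examples
#' f <- fit_psychometric(
#'   tibble::tibble(ild_db = c(-4, -1, 1, 4), k_right = c(5, 30, 70, 95), n = 100),
#'   "probit"
#' )
#' jnd(f)
#' @export
jnd <- function(fit, lapse_corrected = FALSE) {
  stopifnot(inherits(fit, "ild_fit"))
  undefined <- function(reason) structure(NA_real_, reason = reason)
  if (fit$model == "null") return(undefined("null model"))
  a <- fit$params$alpha
  if (!is.finite(a) || a == 0) return(undefined("alpha = 0"))
  if (fit$model == "linear") return(0.25 / abs(a))
  g <- if (lapse_corrected) 0 else fit$params$gamma
  if (g >= 0.5) return(undefined("gamma >= 0.5: 75% unreachable"))
  qnorm((0.75 - g / 2) / (1 - g)) / abs(a)
}

#' Slope of the fitted psychometric curve at ILD = 0
#'
#' Sensitivity expressed as the % change in "right"-response probability per
#' dB of ILD at the midpoint: `100 * alpha * dnorm(beta) * (1 - gamma)` for
#' the probit model and `100 * alpha` for the bounded linear model (0 when
#' the linear fit is already clipped at ILD = 0, i.e. `|delta| >= 0.5`).
#' Undefined for the null model. The sign carries the response direction
#' (negative for left-preferring fits).
#'
#' @param fit An `ild_fit`.
#' @return Slope in % per dB (`NA` for the null model).
#' @export
slope_at_zero <- function(fit) {
  stopifnot(inherits(fit, "ild_fit"))
  if (fit$model == "null") return(structure(NA_real_, reason = "null model"))
  if (fit$model == "linear") {
    clipped <- abs(fit$params$delta) >= 0.5
    return(if (clipped) 0 else 100 * fit$params$alpha)
  }
  100 * fit$params$alpha * dnorm(fit$params$beta) * (1 - fit$params$gamma)
}

#' Wilson score interval for a binomial proportion
#'
#' Score-based confidence interval for the probability underlying `k`
#' successes in `n` trials, with good coverage at small `n` and near the
#' boundaries. The critical value is the standard-normal quantile at
#' `(1 + confidence) / 2`, so any confidence level works.
#'
#' @param k Number of successes (vectorized).
#' @param n Number of trials (vectorized).
#' @param confidence Confidence level in (0, 1).
#' @return A tibble with columns `lo` and `hi`; always
#'   `0 <= lo <= k/n <= hi <= 1`.
#' @examples
#' wilson_interval(5, 10)
#' @export
wilson_interval <- function(k, n, confidence = 0.95) {
  if (any(n < 1) || any(k < 0 | k > n)) {
    abort("Need 0 <= k <= n and n >= 1.")
  }
  if (confidence <= 0 || confidence >= 1) abort("`confidence` must be in (0, 1).")
  z <- qnorm((1 + confidence) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble(lo = pmax(centre - half, 0), hi = pmin(centre + half, 1))
}

#' Per-curve sensitivity metrics from fitted models
#'
#' Computes the JND and the slope at ILD = 0 for each selected fit in a
#' [fit_curves()] table, with explicit flags instead of fabricated numbers
#' where a metric is undefined.
#'
#' @param fits A tibble from [fit_curves()] (needs the `fit` list-column).
#' @param lapse_corrected Passed to [jnd()].
#' @return A tibble: `subject`, `pps`, `model`, `jnd_db`,
#'   `slope_pct_per_db`, `jnd_undefined`, `boundary_fit` (fit did not
#'   converge or sits on the parameter boundary).
#' @export
ild_sensitivity <- function(fits, lapse_corrected = FALSE) {
  stopifnot(is.data.frame(fits), "fit" %in% names(fits))
  purrr::map_dfr(seq_len(nrow(fits)), function(i) {
    f <- fits$fit[[i]]
    j <- jnd(f, lapse_corrected = lapse_corrected)
    s <- slope_at_zero(f)
    boundary <- !f$converged ||
      (f$model == "probit" &&
         (abs(f$params$alpha) >= 20 - 1e-6 || f$params$gamma >= 1 - 1e-6))
    tibble(
      subject = fits$subject[i], pps = fits$pps[i], model = f$model,
      jnd_db = as.numeric(j), slope_pct_per_db = as.numeric(s),
      jnd_undefined = is.na(j), boundary_fit = boundary
    )
  })
}

#' Cohort-level summary of sensitivity metrics
#'
#' Medians and means of the JND and slope per pulse rate, excluding undefined
#' JNDs and reporting how many were excluded.
#'
#' @param results A sensitivity tibble from [ild_sensitivity()].
#' @return A tibble, one row per pulse rate: `pps`, `n_subjects`,
#'   `n_jnd_excluded`, `median_jnd_db`, `mean_jnd_db`,
#'   `median_slope_pct_per_db`, `mean_slope_pct_per_db`.
#' @export
summarize_cohort <- function(results) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0) abort("Empty sensitivity table.")
  results |>
    dplyr::group_by(.data$pps) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      n_jnd_excluded = sum(is.na(.data$jnd_db)),
      median_jnd_db = stats::median(.data$jnd_db, na.rm = TRUE),
      mean_jnd_db = mean(.data$jnd_db, na.rm = TRUE),
      median_slope_pct_per_db = stats::median(.data$slope_pct_per_db, na.rm = TRUE),
      mean_slope_pct_per_db = mean(.data$slope_pct_per_db, na.rm = TRUE),
      .groups = "drop"
    )
}
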