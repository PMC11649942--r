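# attach Wilson interval columns unless the summary already carries them
with_wilson <- function(s) {
  if (all(c("lo", "hi") %in% names(s))) return(s)
  dplyr::bind_cols(s, wilson_interval(s$k_right, s$n))
}

#' Plot one fitted psychometric curve
#'
#' Observed proportions of "right" responses with 95% Wilson intervals, the
#' fitted curve, the tangent at ILD = 0 (the slope sensitivity measure) and
#' the 50% chance line.
#'
#' @param object An `ild_fit`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ild_fit <- function(object, ...) {
  pts <- with_wilson(object$data)
  grid <- tibble(
    ild_db = seq(min(pts$ild_db), max(pts$ild_db), length.out = 200)
  )
  grid$p <- predict_model(object$model, object$params, grid$ild_db)

  gg <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$ild_db)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.2, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$k_right / .data$n), size = 2) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$p),
                       colour = "#b2182b", linewidth = 0.8)

  slope <- slope_at_zero(object)
  if (is.finite(slope) && object$model != "null") {
    p0 <- predict_model(object$model, object$params, 0)
    gg <- gg + ggplot2::geom_abline(intercept = p0, slope = slope / 100,
                                    linetype = "dashed", colour = "darkgreen")
  }
  gg +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "ILD (dB, right - left)", y = "p(respond right)",
                  subtitle = sprintf("%s model", object$model)) +
    ggplot2::theme_minimal()
}

#' Grid of psychometric curves for many subjects
#'
#' Faceted panel of per-curve data and selected fits, one facet per
#' (subject, pulse rate).
#'
#' @param fits A [fit_curves()] tibble.
#' @return A ggplot object.
#' @export
plot_psychometric <- function(fits) {
  stopifnot(is.data.frame(fits), "fit" %in% names(fits))
  pts <- purrr::map_dfr(seq_len(nrow(fits)), function(i) {
    f <- fits$fit[[i]]
    dplyr::bind_cols(
      tibble(subject = fits$subject[i], pps = fits$pps[i]),
      with_wilson(f$data)
    )
  })
  curves <- purrr::map_dfr(seq_len(nrow(fits)), function(i) {
    f <- fits$fit[[i]]
    g <- seq(min(f$data$ild_db), max(f$data$ild_db), length.out = 120)
    tibble(subject = fits$subject[i], pps = fits$pps[i], ild_db = g,
           p = predict_model(f$model, f$params, g), model = f$model)
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$ild_db)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.3, colour = "grey55", linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(y = .data$k_right / .data$n), size = 0.8) +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(y = .data$p, colour = .data$model), linewidth = 0.6
    ) +
    ggplot2::scale_colour_manual(
      values = c(probit = "#67001f", linear = "#ef8a62", null = "grey50")
    ) +
    ggplot2::facet_wrap(~ subject + pps, labeller = ggplot2::label_both) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "ILD (dB, right - left)", y = "p(respond right)") +
    ggplot2::theme_minimal()
}

#' Swarm-style cohort plot of sensitivity metrics
#'
#' Distribution of per-subject slopes and JNDs with deterministic horizontal
#' jitter and the cohort median marked.
#'
#' @param results An [ild_sensitivity()] tibble.
#' @return A ggplot object.
#' @export
plot_cohort <- function(results) {
  long <- results |>
    dplyr::select("subject", "pps", slope = "slope_pct_per_db", jnd = "jnd_db") |>
    tidyr::pivot_longer(c("slope", "jnd"), names_to = "measure",
                        values_to = "value") |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(.data$measure) |>
    dplyr::mutate(x = (dplyr::row_number() - (dplyr::n() + 1) / 2) /
                    max(dplyr::n(), 1) * 0.6) |>
    dplyr::ungroup()
  med <- long |>
    dplyr::group_by(.data$measure) |>
    dplyr::summarise(m = stats::median(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$value,
                                     colour = .data$subject)) +
    ggplot2::geom_point(size = 2, show.legend = FALSE) +
    ggplot2::geom_hline(data = med, ggplot2::aes(yintercept = .data$m),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~ .data$measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "sensitivity (slope: %/dB; jnd: dB)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Sensitivity versus pulse rate with the pooled regression line
#'
#' Per-subject points across pulse rates, per-rate means as horizontal bars,
#' and the pooled OLS line on log(pps) for each measure.
#'
#' @param results An [ild_sensitivity()] tibble spanning two or more rates.
#' @param log_base Log base for the regression and the x axis.
#' @return A ggplot object.
#' @export
plot_rate_sensitivity <- function(results, log_base = 10) {
  long <- results |>
    dplyr::select("subject", "pps", slope = "slope_pct_per_db", jnd = "jnd_db") |>
    tidyr::pivot_longer(c("slope", "jnd"), names_to = "measure",
                        values_to = "value") |>
    dplyr::filter(is.finite(.data$value))
  means <- long |>
    dplyr::group_by(.data$pps, .data$measure) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  lines <- purrr::map_dfr(c("slope", "jnd"), function(m) {
    rr <- regress_log_rate(results, m, log_base = log_base)
    grid <- exp(seq(log(min(results$pps)), log(max(results$pps)),
                    length.out = 50))
    tibble(measure = m, pps = grid,
           value = rr$intercept + rr$slope * log(grid, base = log_base))
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pps, y = .data$value)) +
    ggplot2::geom_line(data = lines, colour = "grey50", linewidth = 1) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$subject), size = 2) +
    ggplot2::geom_point(data = means, shape = 95, size = 8, colour = "black") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~ .data$measure, scales = "free_y") +
    ggplot2::labs(x = "pulse rate (pps)",
                  y = "sensitivity (slope: %/dB; jnd: dB)") +
    ggplot2::theme_minimal()
}
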