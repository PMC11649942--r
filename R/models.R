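#' Psychometric model predictions
#'
#' Probability of a "right" response as a function of stimulus ILD under the
#' three candidate response models:
#'
#' * **probit** (cumulative-Gaussian sigmoid with lapses):
#'   `pR = Phi(ILD * alpha + beta) * (1 - gamma) + gamma/2 + delta`,
#'   where `alpha` is the ILD sensitivity (probit units per dB), `beta` an ear
#'   bias (the point of subjective equality sits at `-beta/alpha` dB),
#'   `gamma` in `[0, 1]` a lapse rate compressing both asymptotes towards
#'   chance, and `delta` a spout bias shifting the whole curve vertically.
#' * **bounded linear**: `pR = ILD * alpha + 1/2 + delta`, clipped to `[0, 1]`.
#' * **null** (no ILD sensitivity): `pR = delta`, a constant response
#'   probability; here `delta` is an absolute probability in `[0, 1]`, not an
#'   offset around 1/2.
#'
#' @param ild ILD in dB, right minus left (vectorized).
#' @param alpha Sensitivity slope (per dB); any sign.
#' @param beta Ear bias (probit-argument offset).
#' @param gamma Lapse rate in `[0, 1]`.
#' @param delta Spout bias (probit/linear: additive offset; null: absolute
#'   probability).
#' @return Predicted probability of a "right" response.
#' @examples
#' predict_probit(0, alpha = 0.5)            # 0.5
#' predict_linear(10, alpha = 0.1, delta = 0) # clipped to 1
#' @export
predict_probit <- function(ild, alpha, beta = 0, gamma = 0, delta = 0) {
  if (any(gamma < 0 | gamma > 1)) abort("`gamma` must lie in [0, 1].")
  pnorm(ild * alpha + beta) * (1 - gamma) + gamma / 2 + delta
}

#' @rdname predict_probit
#' @export
predict_linear <- function(ild, alpha, delta = 0) {
  pmin(pmax(ild * alpha + 0.5 + delta, 0), 1)
}

#' @rdname predict_probit
#' @export
predict_null <- function(delta) {
  if (any(delta < 0 | delta > 1)) {
    abort("The null model's `delta` is an absolute probability and must lie in [0, 1].")
  }
  delta
}

# evaluate any of the three models on a vector of ILDs given a params list
predict_model <- function(model, params, ild) {
  switch(model,
    probit = predict_probit(ild, params$alpha, params$beta, params$gamma, params$delta),
    linear = predict_linear(ild, params$alpha, params$delta),
    null = rep(predict_null(params$delta), length(ild)),
    abort(sprintf("Unknown model kind '%s'.", model))
  )
}

#' Aggregate trials into a per-ILD binomial summary
#'
#' Collapses trial records to right-response counts per tested ILD — the
#' sufficient statistics for all three psychometric models — optionally within
#' grouping columns (`subject`, `pps`) when present, and attaches the Wilson
#' score interval for the underlying probability of a "right" response.
#'
#' @param trials A data frame with at least `ild_db` and `response`
#'   (`"left"`/`"right"`); `subject` and `pps` columns are used as groups if
#'   present.
#' @param confidence Confidence level for the Wilson interval.
#' @return A tibble with columns (groups,) `ild_db`, `k_right`, `n`, `p_hat`,
#'   `lo`, `hi`, sorted by ILD within group.
#' @export
binomial_summary <- function(trials, confidence = 0.95) {
  stopifnot(is.data.frame(trials))
  if (!all(c("ild_db", "response") %in% names(trials))) {
    abort("`trials` must contain columns `ild_db` and `response`.")
  }
  grp <- intersect(c("subject", "pps"), names(trials))
  out <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "ild_db")))) |>
    dplyr::summarise(
      k_right = sum(.data$response == "right"),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(grp, "ild_db")))) |>
    dplyr::mutate(p_hat = .data$k_right / .data$n)
  ci <- wilson_interval(out$k_right, out$n, confidence)
  dplyr::bind_cols(out, ci)
}

#' Binomial log-likelihood of a psychometric model
#'
#' Log-likelihood of per-ILD right-response counts under a model's predicted
#' probabilities: `sum(k * log(p) + (n - k) * log(1 - p))`, with predictions
#' clamped to `[eps, 1 - eps]` so boundary predictions stay finite. Equivalent
#' to the trial-level Bernoulli log-likelihood up to the additive
#' `log choose(n, k)` terms, which do not depend on the parameters.
#'
#' @param model One of `"probit"`, `"linear"`, `"null"`.
#' @param params Named list of parameters for that model.
#' @param summary A binomial summary with columns `ild_db`, `k_right`, `n`.
#' @param eps Clamp for log arguments.
#' @return The log-likelihood (non-positive for admissible data).
#' @export
log_likelihood <- function(model, params, summary, eps = 1e-9) {
  validate_summary(summary)
  p <- predict_model(model, params, summary$ild_db)
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(summary$k_right * log(p) + (summary$n - summary$k_right) * log(1 - p))
}

validate_summary <- function(summary) {
  if (!is.data.frame(summary) ||
      !all(c("ild_db", "k_right", "n") %in% names(summary))) {
    abort("A binomial summary needs columns `ild_db`, `k_right`, `n`.")
  }
  if (any(summary$n < 1) || any(summary$k_right < 0 | summary$k_right > summary$n)) {
    abort("Counts must satisfy 0 <= k_right <= n, n >= 1.")
  }
  if (anyDuplicated(summary$ild_db)) abort("ILD values in a summary must be unique.")
  invisible(summary)
}

new_ild_fit <- function(model, params, loglik, n_trials, converged,
                        n_restarts_used, data) {
  structure(
    list(
      model = model,
      params = params,
      loglik = loglik,
      n_params = switch(model, probit = 4L, linear = 2L, null = 1L),
      n_trials = n_trials,
      converged = converged,
      n_restarts_used = n_restarts_used,
      data = data
    ),
    class = "ild_fit"
  )
}

#' @export
print.ild_fit <- function(x, ...) {
  cat(sprintf(
    "<ild_fit> %s model, %d trials, logLik %.3f%s\n  %s\n",
    x$model, x$n_trials, x$loglik,
    if (x$converged) "" else " (NOT converged)",
    paste(sprintf("%s = %.4g", names(x$params), unlist(x$params)), collapse = ", ")
  ))
  invisible(x)
}

#' @export
tidy.ild_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unlist(x$params, use.names = FALSE))
}

#' @export
glance.ild_fit <- function(x, ...) {
  tibble(
    model = x$model, loglik = x$loglik, n_params = x$n_params,
    n_trials = x$n_trials, converged = x$converged,
    n_restarts_used = x$n_restarts_used
  )
}

# deterministic multi-start lattice for the probit model; sign-symmetric so
# that mirrored datasets (ILD -> -ILD, L <-> R) traverse mirrored starts
probit_starts <- function() {
  g <- expand.grid(
    alpha = c(-0.5, -0.05, 0.05, 0.5),
    beta = c(-0.25, 0.25),
    gamma = c(0.02, 0.2),
    delta = 0
  )
  as.matrix(g)
}

#' Maximum-likelihood fit of one psychometric model
#'
#' Fits the probit-with-lapse, bounded-linear or null model to a per-ILD
#' binomial summary by maximizing the binomial log-likelihood.
#'
#' The null model has the closed-form MLE `delta = sum(k) / sum(n)`. The
#' linear and probit models are fit by multi-start local optimization (the
#' probit from a fixed 16-point lattice of starting values, since lapse models
#' have local optima), under the constraints `gamma` in `[0, 1]` and all
#' predicted probabilities within `[0, 1]` over the observed ILD range
#' (enforced as a box plus a quadratic out-of-range penalty). The best restart
#' is returned; `converged` reports the optimizer's status for that restart
#' honestly.
#'
#' @param summary A binomial summary (see [binomial_summary()]), one curve:
#'   columns `ild_db`, `k_right`, `n`.
#' @param model `"probit"`, `"linear"` or `"null"`.
#' @param eps Likelihood clamp, passed to [log_likelihood()].
#' @return An `ild_fit` object.
#' @examples
#' s <- tibble::tibble(ild_db = c(-4, -2, 2, 4), k_right = c(2, 8, 32, 38), n = 40)
#' fit_psychometric(s, "probit")
#' @export
fit_psychometric <- function(summary, model = c("probit", "linear", "null"),
                             eps = 1e-9) {
  model <- match.arg(model)
  validate_summary(summary)
  n_trials <- sum(summary$n)
  p_pool <- sum(summary$k_right) / n_trials

  if (all(summary$k_right == 0) || all(summary$k_right == summary$n)) {
    warn("All responses fall on one side; the MLE lies on the parameter boundary.")
  }

  if (model == "null") {
    fit <- new_ild_fit(
      "null", list(delta = p_pool),
      log_likelihood("null", list(delta = p_pool), summary, eps),
      n_trials, converged = TRUE, n_restarts_used = 0L, data = summary
    )
    return(fit)
  }

  if (length(unique(summary$ild_db)) < 2) {
    abort("Fitting the linear or probit model needs at least 2 distinct ILDs.")
  }

  ild <- summary$ild_db
  k <- summary$k_right
  n <- summary$n

  if (model == "linear") {
    nll <- function(th) {
      # delta beyond +/-0.5 pins the curve at ILD = 0; keep it boxed softly
      pen <- 1e6 * (max(abs(th[2]) - 0.5, 0))^2
      p <- pmin(pmax(predict_linear(ild, th[1], th[2]), eps), 1 - eps)
      -sum(k * log(p) + (n - k) * log(1 - p)) + pen
    }
    starts <- rbind(
      expand.grid(alpha = c(-0.3, -0.1, -0.02, 0.02, 0.1, 0.3), delta = 0),
      data.frame(alpha = 0, delta = min(max(p_pool - 0.5, -0.5), 0.5))
    )
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      res <- tryCatch(
        optim(as.numeric(starts[i, ]), nll, method = "Nelder-Mead",
              control = list(maxit = 1000)),
        error = function(e) NULL
      )
      if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
    }
    params <- list(alpha = best$par[1],
                   delta = min(max(best$par[2], -0.5), 0.5))
    return(new_ild_fit(
      "linear", params, log_likelihood("linear", params, summary, eps),
      n_trials, converged = best$convergence == 0,
      n_restarts_used = nrow(starts), data = summary
    ))
  }

  # probit: box on (alpha, beta, gamma, delta) plus penalty keeping the
  # predicted probabilities inside [0, 1] over the observed ILD range
  nll <- function(th) {
    p <- pnorm(ild * th[1] + th[2]) * (1 - th[3]) + th[3] / 2 + th[4]
    pen <- 1e6 * sum(pmax(p - 1, 0)^2 + pmax(-p, 0)^2)
    p <- pmin(pmax(p, eps), 1 - eps)
    -sum(k * log(p) + (n - k) * log(1 - p)) + pen
  }
  lower <- c(-20, -10, 0, -0.5)
  upper <- c(20, 10, 1, 0.5)
  starts <- probit_starts()
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[i, ], nll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) abort("The probit fit failed from every starting value.")
  params <- list(alpha = best$par[[1]], beta = best$par[[2]],
                 gamma = best$par[[3]], delta = best$par[[4]])
  new_ild_fit(
    "probit", params, log_likelihood("probit", params, summary, eps),
    n_trials, converged = best$convergence == 0,
    n_restarts_used = nrow(starts), data = summary
  )
}

#' Deviance-based selection among the three psychometric models
#'
#' Sequential likelihood-ratio (deviance) tests along the chain
#' null -> linear -> probit: the richer model is accepted if and only if twice
#' the log-likelihood gain exceeds the chi-squared critical value with degrees
#' of freedom equal to the difference in free parameters (1 for null vs
#' linear, 2 for linear vs probit) at the given significance level. The chain
#' stops at the first non-rejection, and a test statistic exactly at the
#' critical value resolves to the simpler model. The bounded-linear model is
#' not strictly nested in the probit; the sequential chain mirrors how the
#' three candidates are compared in practice, and an AIC-based comparison is
#' available as an alternative.
#'
#' @param fits A list of the three `ild_fit` objects (null, linear, probit, in
#'   any order) fitted to the same summary.
#' @param alpha_level Significance level for each deviance test.
#' @param method `"deviance"` (sequential likelihood-ratio chain, default) or
#'   `"aic"` (pick the smallest AIC; fallback for the non-nested pair).
#' @return An object of class `ild_selection`: list with `selected` (the
#'   chosen `ild_fit`), `model` and `tests` (tibble of comparisons with
#'   deviance, df, p-value and acceptance).
#' @export
select_model <- function(fits, alpha_level = 0.05,
                         method = c("deviance", "aic")) {
  method <- match.arg(method)
  stopifnot(is.list(fits), length(fits) == 3)
  kinds <- vapply(fits, function(f) f$model, character(1))
  if (!setequal(kinds, c("null", "linear", "probit"))) {
    abort("`fits` must contain exactly one null, one linear and one probit fit.")
  }
  names(fits) <- kinds
  ntr <- vapply(fits, function(f) f$n_trials, numeric(1))
  if (length(unique(ntr)) != 1) {
    abort("All three fits must be computed on the same data (n_trials differ).")
  }

  if (method == "aic") {
    aic <- vapply(fits, function(f) 2 * f$n_params - 2 * f$loglik, numeric(1))
    sel <- names(which.min(aic))
    tests <- tibble(
      comparison = paste0("aic_", names(aic)), deviance = NA_real_,
      df = NA_integer_, p_value = NA_real_, statistic = unname(aic),
      accepted_richer = NA
    )
    return(structure(list(selected = fits[[sel]], model = sel, tests = tests),
                     class = "ild_selection"))
  }

  d1 <- 2 * (fits$linear$loglik - fits$null$loglik)
  crit1 <- qchisq(1 - alpha_level, df = 1)
  p1 <- pchisq(d1, df = 1, lower.tail = FALSE)
  take_linear <- d1 > crit1

  d2 <- 2 * (fits$probit$loglik - fits$linear$loglik)
  crit2 <- qchisq(1 - alpha_level, df = 2)
  p2 <- pchisq(d2, df = 2, lower.tail = FALSE)
  take_probit <- take_linear && d2 > crit2

  sel <- if (take_probit) "probit" else if (take_linear) "linear" else "null"
  tests <- tibble(
    comparison = c("linear_vs_null", "probit_vs_linear"),
    deviance = c(d1, d2),
    df = c(1L, 2L),
    p_value = c(p1, p2),
    statistic = c(d1, d2),
    accepted_richer = c(take_linear, take_probit)
  )
  structure(list(selected = fits[[sel]], model = sel, tests = tests),
            class = "ild_selection")
}

#' @export
print.ild_selection <- function(x, ...) {
  cat(sprintf("<ild_selection> selected: %s\n", x$model))
  print(x$tests)
  invisible(x)
}

#' Fit all three models to one curve and select among them
#'
#' Convenience wrapper: fits null, linear and probit to the same binomial
#' summary and runs [select_model()].
#'
#' @inheritParams fit_psychometric
#' @inheritParams select_model
#' @return An `ild_selection` with an extra element `fits` (all three fits).
#' @export
fit_and_select <- function(summary, alpha_level = 0.05,
                           method = c("deviance", "aic")) {
  fits <- lapply(c("null", "linear", "probit"), function(m) {
    fit_psychometric(summary, m)
  })
  sel <- select_model(fits, alpha_level = alpha_level, method = method)
  sel$fits <- stats::setNames(fits, c("null", "linear", "probit"))
  sel
}

#' Fit and select psychometric models for every curve in a trial table
#'
#' Groups trials by `subject` and `pps`, fits the three candidate models to
#' each curve, selects among them by the deviance chain, and returns one row
#' per curve with the selected model's parameters and the deviance-test
#' p-values. Fit objects are kept in a list-column for plotting and further
#' inspection.
#'
#' @param trials A trial table (see [simulate_trials()] / [read_trials()]).
#' @inheritParams select_model
#' @return A tibble with columns `subject`, `pps`, `model`, `alpha`, `beta`,
#'   `gamma`, `delta`, `loglik`, `n_trials`, `converged`,
#'   `p_linear_vs_null`, `p_probit_vs_linear`, and list-columns `fit`
#'   (selected `ild_fit`) and `selection` (`ild_selection`).
#' @export
fit_curves <- function(trials, alpha_level = 0.05) {
  stopifnot(is.data.frame(trials))
  if (!"subject" %in% names(trials)) trials$subject <- "s1"
  if (!"pps" %in% names(trials)) trials$pps <- NA_real_
  trials |>
    dplyr::group_by(.data$subject, .data$pps) |>
    dplyr::group_modify(function(d, key) {
      s <- binomial_summary(d)
      sel <- fit_and_select(s, alpha_level = alpha_level)
      f <- sel$selected
      p <- f$params
      tibble(
        model = f$model,
        alpha = p$alpha %||% NA_real_,
        beta = p$beta %||% NA_real_,
        gamma = p$gamma %||% NA_real_,
        delta = p$delta,
        loglik = f$loglik,
        n_trials = f$n_trials,
        converged = f$converged,
        p_linear_vs_null = sel$tests$p_value[1],
        p_probit_vs_linear = sel$tests$p_value[2],
        fit = list(f),
        selection = list(sel)
      )
    }) |>
    dplyr::ungroup()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
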