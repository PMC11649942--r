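test_that("model predictions evaluate their defining equations", {
  # midpoint and lapse-only limits
  expect_equal(predict_probit(0, alpha = 3.7), 0.5)
  expect_equal(predict_probit(c(-5, 0, 2), alpha = 2, gamma = 1),
               rep(0.5, 3))
  # frozen value of Phi(1.3) * 0.9 + 0.05 + 0.02
  expect_equal(predict_probit(2, 0.5, 0.3, 0.1, 0.02), 0.8828796,
               tolerance = 1e-7)

  expect_equal(predict_linear(0, 0.1), 0.5)
  expect_equal(predict_linear(10, 0.1), 1.0)
  expect_equal(predict_linear(1, 0.14, 0.05), 0.69)

  expect_equal(predict_null(0.5), 0.5)
  expect_equal(predict_null(0), 0)
  expect_error(predict_null(1.2), "absolute probability")

  # all predictors stay in [0, 1] for admissible parameters
  set.seed(4)
  for (i in 1:25) {
    a <- runif(1, -2, 2); b <- runif(1, -1, 1); g <- runif(1)
    x <- runif(7, -8, 8)
    expect_true(all(predict_probit(x, a, b, g, 0) >= g / 2 - 1e-12))
    expect_true(all(predict_linear(x, a, runif(1, -0.5, 0.5)) >= 0))
    expect_true(all(predict_linear(x, a, runif(1, -0.5, 0.5)) <= 1))
  }

  # probit non-decreasing in ILD for alpha > 0, gamma < 1
  x <- seq(-8, 8, by = 0.25)
  p <- predict_probit(x, 0.7, -0.3, 0.2, 0.01)
  expect_true(all(diff(p) >= 0))
})

test_that("the binomial log-likelihood matches trial-level Bernoulli sums", {
  s <- tibble::tibble(ild_db = c(-2, 1), k_right = c(5, 0), n = c(10, 8))
  expect_equal(log_likelihood("null", list(delta = 0.5), s),
               18 * log(0.5))

  # near-perfect prediction gives log-likelihood ~ 0
  perfect <- tibble::tibble(ild_db = c(-3, 3), k_right = c(0, 20), n = 20)
  expect_equal(log_likelihood("probit", list(alpha = 50, beta = 0, gamma = 0,
                                             delta = 0), perfect),
               0, tolerance = 1e-4)

  # summary likelihood equals the per-trial Bernoulli sum (the binomial
  # coefficient is a parameter-free constant and is omitted by design)
  tr <- simulate_trials(virtual_subject("r", alpha = 0.4, gamma = 0.05),
                        session_design(seed = 13, trials_per_session = 98,
                                       n_sessions = 1))
  s2 <- binomial_summary(tr)
  pars <- list(alpha = 0.3, beta = 0.1, gamma = 0.06, delta = 0.01)
  p_tr <- predict_probit(tr$ild_db, pars$alpha, pars$beta, pars$gamma, pars$delta)
  bernoulli <- sum(ifelse(tr$response == "right", log(p_tr), log(1 - p_tr)))
  expect_equal(log_likelihood("probit", pars, s2), bernoulli, tolerance = 1e-9)

  expect_error(log_likelihood("null", list(delta = 0.5),
                              tibble::tibble(ild_db = 1, k_right = 5, n = 4)),
               "k_right")
})

test_that("the null MLE is the pooled proportion", {
  s <- tibble::tibble(ild_db = c(-6, -2, 2, 6), k_right = c(50, 60, 90, 100),
                      n = 200)
  fit <- fit_psychometric(s, "null")
  expect_equal(fit$params$delta, 300 / 800)
  expect_equal(fit$n_params, 1L)
  expect_true(fit$converged)
})

test_that("probit fits recover simulated parameters on one curve", {
  s <- simulate_summary(seed = 101, alpha = 0.4, gamma = 0.05)
  fit <- fit_psychometric(s, "probit")
  expect_true(fit$converged)
  expect_equal(fit$n_params, 4L)
  expect_lt(fit$loglik, 0)
  expect_lt(abs(fit$params$alpha - 0.4), 0.15)
  expect_true(fit$params$gamma >= 0 && fit$params$gamma <= 1)
  # constrained predictions stay inside [0, 1] over the observed range
  p <- predict_probit(s$ild_db, fit$params$alpha, fit$params$beta,
                      fit$params$gamma, fit$params$delta)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("the optimizer matches a coarse 4-D grid search", {
  s <- simulate_summary(seed = 55, alpha = 0.5, beta = 0.2, gamma = 0.1,
                        n_sessions = 1, trials_per_session = 140)
  fit <- fit_psychometric(s, "probit")
  grid <- expand.grid(
    alpha = seq(-1, 1, by = 0.1), beta = seq(-0.75, 0.75, by = 0.25),
    gamma = c(0, 0.05, 0.1, 0.2, 0.35), delta = seq(-0.1, 0.1, by = 0.05)
  )
  ll <- vapply(seq_len(nrow(grid)), function(i) {
    p <- predict_probit(s$ild_db, grid$alpha[i], grid$beta[i],
                        grid$gamma[i], grid$delta[i])
    if (any(p < 0 | p > 1)) return(-Inf)
    log_likelihood("probit", as.list(grid[i, ]), s)
  }, numeric(1))
  expect_gte(fit$loglik, max(ll) - 1e-3)
})

test_that("degenerate one-sided data is flagged, not silently fit", {
  s <- tibble::tibble(ild_db = c(-2, 2), k_right = c(0, 0), n = 30)
  expect_warning(fit_psychometric(s, "null"), "boundary")
})

test_that("mirror symmetry: negating ILDs and swapping responses flips biases", {
  s <- simulate_summary(seed = 77, alpha = 0.45, beta = 0.3, gamma = 0.08,
                        delta = 0.01)
  mirrored <- tibble::tibble(ild_db = -s$ild_db, k_right = s$n - s$k_right,
                             n = s$n)
  f1 <- fit_psychometric(s, "probit")
  f2 <- fit_psychometric(mirrored, "probit")
  expect_equal(f2$params$alpha, f1$params$alpha, tolerance = 1e-4)
  expect_equal(f2$params$beta, -f1$params$beta, tolerance = 1e-4)
  expect_equal(f2$params$delta, -f1$params$delta, tolerance = 1e-4)
  expect_equal(f2$params$gamma, f1$params$gamma, tolerance = 1e-4)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-8)
})

test_that("richer models never lose log-likelihood to nested simpler ones", {
  set.seed(200)
  for (seed in c(201, 202, 203, 204)) {
    s <- simulate_summary(seed = seed, alpha = runif(1, 0, 0.8),
                          gamma = runif(1, 0, 0.3), n_sessions = 1)
    sel <- fit_and_select(s)
    ll <- vapply(sel$fits, function(f) f$loglik, numeric(1))
    expect_gte(ll[["linear"]], ll[["null"]] - 1e-6)
    # the selected model never has lower log-likelihood than a simpler one
    # it was preferred over
    if (sel$model == "probit") expect_gte(ll[["probit"]], ll[["linear"]] - 1e-6)
    if (sel$model == "linear") expect_gte(ll[["linear"]], ll[["null"]] - 1e-6)
  }
})

test_that("deviance selection walks the null -> linear -> probit chain", {
  s <- simulate_summary(seed = 301, alpha = 1, gamma = 0.05)
  sel <- fit_and_select(s)
  expect_s3_class(sel, "ild_selection")
  expect_equal(sel$model, "probit")
  expect_equal(sel$tests$df, c(1L, 2L))
  expect_true(all(sel$tests$accepted_richer))
  expect_true(all(sel$tests$p_value <= 1 & sel$tests$p_value >= 0))

  # mismatched data is rejected
  other <- fit_psychometric(simulate_summary(seed = 302, n_sessions = 2), "null")
  expect_error(select_model(list(other, sel$fits$linear, sel$fits$probit)),
               "n_trials")

  # a statistic exactly at the critical value resolves to the simpler model
  mk <- function(model, ll, np) {
    structure(list(model = model, params = list(delta = 0.5), loglik = ll,
                   n_params = np, n_trials = 800, converged = TRUE,
                   n_restarts_used = 0L, data = NULL), class = "ild_fit")
  }
  half_crit <- stats::qchisq(0.95, 1) / 2
  tie <- select_model(list(mk("null", -half_crit, 1L), mk("linear", 0, 2L),
                           mk("probit", 0, 4L)))
  expect_equal(tie$model, "null")

  # AIC fallback for the non-nested comparison
  aic <- select_model(list(mk("null", -500, 1L), mk("linear", -450, 2L),
                           mk("probit", -449.5, 4L)), method = "aic")
  expect_equal(aic$model, "linear")
})

test_that("fit_curves returns one tidy row per curve with broom accessors", {
  coh <- make_cohort(2, seed = 3)
  tr <- simulate_trials(coh, session_design(seed = 4, trials_per_session = 100,
                                            n_sessions = 2))
  fits <- fit_curves(tr)
  expect_equal(nrow(fits), 2)
  expect_true(all(fits$model %in% c("probit", "linear", "null")))
  expect_true(all(fits$n_trials == 200))

  td <- tidy(fits$fit[[1]])
  expect_named(td, c("term", "estimate"))
  gl <- glance(fits$fit[[1]])
  expect_equal(gl$model, fits$model[1])
  expect_s3_class(autoplot(fits$fit[[1]]), "ggplot")
})
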