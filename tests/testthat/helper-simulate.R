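# Simulate one ~800-trial psychometric curve from a probit ground truth and
# return its per-ILD binomial summary. Used across the model and metric tests.
simulate_summary <- function(seed, alpha = 0.4, beta = 0, gamma = 0.05,
                             delta = 0, n_sessions = 4,
                             trials_per_session = 200) {
  subj <- virtual_subject("sim", alpha = alpha, beta = beta, gamma = gamma,
                          delta = delta)
  design <- session_design(trials_per_session = trials_per_session,
                           n_sessions = n_sessions, seed = seed)
  binomial_summary(simulate_trials(subj, design))
}

# Numerically invert a fitted curve (spout bias removed) to the ILD giving
# response probability `p`. Independent route to the closed-form JND.
invert_curve <- function(fit, p, lower = -1000, upper = 1000) {
  g <- function(x) {
    pred <- switch(fit$model,
      probit = predict_probit(x, fit$params$alpha, fit$params$beta,
                              fit$params$gamma, 0),
      linear = x * fit$params$alpha + 0.5
    )
    pred - p
  }
  stats::uniroot(g, c(lower, upper), tol = 1e-12)$root
}
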