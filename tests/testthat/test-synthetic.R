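test_that("trial simulation is deterministic and stream-stable per subject", {
  a <- virtual_subject("rA", alpha = 0.4, gamma = 0.05)
  b <- virtual_subject("rB", alpha = 0.6, gamma = 0.02)
  design <- session_design(seed = 99, trials_per_session = 56, n_sessions = 2)

  t1 <- simulate_trials(a, design)
  t2 <- simulate_trials(a, design)
  expect_identical(t1, t2)

  # adding a subject never perturbs an existing subject's records
  both <- simulate_trials(dplyr::bind_rows(a, b), design)
  expect_identical(dplyr::filter(both, subject == "rA"), t1)

  # conservation: trials_per_session x n_sessions per (subject, rate)
  expect_equal(nrow(t1), 56 * 2)
  counts <- dplyr::count(both, subject)
  expect_true(all(counts$n == 112))
})

test_that("trials are allocated to ILDs in balanced blocks", {
  subj <- virtual_subject("r1", alpha = 0.4)
  # 3 blocks of the 14-ILD set + remainder of 6
  design <- session_design(seed = 5, trials_per_session = 48, n_sessions = 1)
  tr <- simulate_trials(subj, design)
  per_ild <- dplyr::count(tr, ild_db)
  expect_equal(nrow(per_ild), 14)
  expect_true(all(per_ild$n %in% c(3, 4)))
  expect_equal(sum(per_ild$n == 4), 6)
})

test_that("the correct flag follows the sign convention, coin at zero ILD", {
  subj <- virtual_subject("r1", alpha = 0.8, gamma = 0.1)
  design <- session_design(seed = 3, trials_per_session = 140, n_sessions = 1)
  tr <- simulate_trials(subj, design)
  expect_identical(
    tr$correct,
    (tr$response == "right" & tr$ild_db > 0) |
      (tr$response == "left" & tr$ild_db < 0)
  )

  with0 <- session_design(ild_set = c(-2, 0, 2), seed = 3,
                          trials_per_session = 300, n_sessions = 1)
  tr0 <- simulate_trials(subj, with0) |> dplyr::filter(ild_db == 0)
  expect_gt(nrow(tr0), 50)
  # no-information trials: correct is a fair coin, independent of response
  expect_true(mean(tr0$correct) > 0.35 && mean(tr0$correct) < 0.65)
  expect_true(any(tr0$correct) && !all(tr0$correct))
})

test_that("responses follow the ground-truth psychometric probabilities", {
  # full lapse = pure guessing regardless of sensitivity
  lapsy <- virtual_subject("r1", alpha = 5, gamma = 1)
  d <- session_design(seed = 21, trials_per_session = 200, n_sessions = 10)
  tr <- simulate_trials(lapsy, d)
  pc <- mean(tr$correct)
  expect_lt(abs(pc - 0.5), 3 * sqrt(0.25 / nrow(tr)) + 0.01)

  # saturation: steep sensitivity pins the extremes
  steep <- virtual_subject("r2", alpha = 5)
  tr2 <- simulate_trials(steep, session_design(seed = 22))
  p6 <- mean(tr2$response[tr2$ild_db == 6] == "right")
  expect_gt(p6, 0.99)

  # empirical proportions track exact Bernoulli probabilities within 3 SD
  med <- virtual_subject("r3", alpha = 0.4, gamma = 0.05)
  tr3 <- simulate_trials(med, session_design(seed = 23))
  chk <- tr3 |>
    dplyr::group_by(ild_db) |>
    dplyr::summarise(p_emp = mean(response == "right"),
                     p_true = truth_p_right[1], n = dplyr::n())
  expect_true(all(abs(chk$p_emp - chk$p_true) <=
                    3 * sqrt(chk$p_true * (1 - chk$p_true) / chk$n)))
})

test_that("empirical response rates converge to truth at large n", {
  subj <- virtual_subject("big", alpha = 0.4, beta = 0.2, gamma = 0.08,
                          delta = 0.01)
  design <- session_design(ild_set = c(-4, -1, 1, 4), seed = 31,
                           trials_per_session = 400000, n_sessions = 1)
  tr <- simulate_trials(subj, design)
  chk <- tr |>
    dplyr::group_by(ild_db) |>
    dplyr::summarise(p_emp = mean(response == "right"),
                     p_true = truth_p_right[1])
  expect_true(all(abs(chk$p_emp - chk$p_true) < 0.01))
})

test_that("invalid ground truths are rejected before simulation", {
  bad <- virtual_subject("x", alpha = 0.4, gamma = 0.05, delta = 0.4)
  expect_error(simulate_trials(bad, session_design(seed = 1)), "outside")
  expect_error(
    simulate_trials(virtual_subject("x", alpha = 1, gamma = 1.2),
                    session_design(seed = 1)),
    "gamma"
  )
})

test_that("the audibility control collapses performance near threshold", {
  subj <- virtual_subject("c1", alpha = 0.8, gamma = 0.02, delta = 0.01,
                          threshold_db = 0)
  design <- session_design(seed = 41)

  # comfortably suprathreshold: identical to the plain simulation
  high <- simulate_audibility_control(subj, design, abl_offsets = 20)
  plain <- simulate_trials(subj, design)
  expect_identical(high |> dplyr::select(-abl_offset_db) |>
                     dplyr::mutate(abl_db = design$abl_db), plain)

  # ABL at threshold: every trial has the quieter ear sub-threshold
  at <- simulate_audibility_control(subj, design, abl_offsets = 0)
  expect_true(all(abs(at$truth_p_right - (0.5 + 0.01)) < 1e-12))

  # end to end: the control curve's JND blows up relative to normal
  fit_at <- fit_psychometric(binomial_summary(at), "probit")
  fit_pl <- fit_psychometric(binomial_summary(plain), "probit")
  j_at <- jnd(fit_at)
  expect_true(is.na(j_at) || j_at > 3 * jnd(fit_pl))
})

test_that("partial audibility flattens only the affected extremes", {
  subj <- virtual_subject("c2", alpha = 0.8, threshold_db = 0)
  design <- session_design(seed = 42, trials_per_session = 140, n_sessions = 1)
  # quieter ear dips under threshold only at |ILD| = 6 (level 2.7 - 3 < 0)
  part <- simulate_audibility_control(subj, design, abl_offsets = 2.7)
  flat <- part |> dplyr::filter(abs(ild_db) == 6)
  rest <- part |> dplyr::filter(abs(ild_db) < 6)
  expect_true(all(flat$truth_p_right == 0.5))
  expect_identical(rest$truth_p_right,
                   predict_probit(rest$ild_db, 0.8))
})

test_that("synthetic cohorts are valid, distinct and reproducible", {
  coh <- make_cohort(24, seed = 7)
  expect_equal(nrow(coh), 24)
  expect_equal(dplyr::n_distinct(coh$subject), 24)
  expect_true(all(coh$gamma >= 0 & coh$gamma <= 1))
  # every drawn truth predicts probabilities inside [0, 1] over +/-6 dB
  for (i in seq_len(nrow(coh))) {
    p <- predict_probit(c(-6, 6), coh$alpha[i], coh$beta[i],
                        coh$gamma[i], coh$delta[i])
    expect_true(all(p >= 0 & p <= 1))
  }

  expect_identical(make_cohort(24, seed = 7), coh)
  expect_equal(nrow(make_cohort(0)), 0)

  # sensitivity declines with pulse rate within subject
  multi <- make_cohort(3, pulse_rates = c(300, 2400), seed = 9)
  wide <- tidyr::pivot_wider(multi[c("subject", "pps", "alpha")],
                             names_from = "pps", values_from = "alpha")
  expect_true(all(wide$`300` > wide$`2400`))
})
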