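#' Session design for a simulated lateralization experiment
#'
#' Describes the trial structure of a 2AFC ILD lateralization study: the set
#' of tested ILDs, trials per session, number of sessions, pulse rates and
#' average binaural level. Defaults follow the typical design: ILDs
#' +/-{0.5, 1, 2, 3, 4, 5, 6} dB, about 200 trials per session, 4 sessions
#' (so ~800 trials per psychometric curve) at 900 pps. Trials are allocated
#' to ILDs in balanced randomized blocks: each block is one shuffled pass
#' through the ILD set, and any remainder is drawn without replacement, so
#' per-ILD counts are equal up to the remainder.
#'
#' @param ild_set Tested ILD values in dB. Zero is excluded from the default;
#'   if supplied, zero-ILD trials carry no information and their `correct`
#'   flag is assigned by fair coin.
#' @param trials_per_session Trials per session.
#' @param n_sessions Number of sessions per (subject, pulse rate).
#' @param pulse_rates Pulse rates (pps) at which curves are collected.
#' @param abl_db Average binaural level in dB.
#' @param seed Master seed; every (subject, pulse rate) cell derives its own
#'   stream from it, so adding subjects never perturbs existing ones.
#' @return A `session_design` list.
#' @export
session_design <- function(ild_set = c(-(6:1), -0.5, 0.5, 1:6),
                           trials_per_session = 200,
                           n_sessions = 4,
                           pulse_rates = 900,
                           abl_db = 10,
                           seed = 1L) {
  if (length(ild_set) == 0 || anyDuplicated(ild_set)) {
    abort("`ild_set` must be non-empty with no duplicated values.")
  }
  stopifnot(trials_per_session >= 1, n_sessions >= 1,
            all(pulse_rates > 0), is.finite(abl_db))
  structure(
    list(
      ild_set = sort(ild_set),
      trials_per_session = as.integer(trials_per_session),
      n_sessions = as.integer(n_sessions),
      pulse_rates = pulse_rates,
      abl_db = abl_db,
      seed = as.integer(seed)
    ),
    class = "session_design"
  )
}

#' Define a virtual subject's ground-truth psychometric parameters
#'
#' One row per (subject, pulse rate) with the true probit-with-lapse
#' parameters used to draw Bernoulli responses. The probit is the most
#' general of the three candidate models; a null ground truth is obtained
#' with `alpha = 0`.
#'
#' @param subject Subject label.
#' @param pps Pulse rate(s) the truth applies to.
#' @param alpha,beta,gamma,delta True psychometric parameters (see
#'   [predict_probit()]).
#' @param threshold_db Optional audibility threshold in dB for the monaural
#'   control simulation ([simulate_audibility_control()]).
#' @return A tibble with columns `subject`, `pps`, `alpha`, `beta`, `gamma`,
#'   `delta`, `threshold_db`.
#' @export
virtual_subject <- function(subject, pps = 900, alpha, beta = 0, gamma = 0,
                            delta = 0, threshold_db = NA_real_) {
  tibble(
    subject = as.character(subject), pps = pps,
    alpha = alpha, beta = beta, gamma = gamma, delta = delta,
    threshold_db = threshold_db
  )
}

# check that a set of truth rows yields probabilities in [0,1] over the design
validate_truth <- function(subjects, ild_set) {
  need <- c("subject", "pps", "alpha", "beta", "gamma", "delta")
  if (!is.data.frame(subjects) || !all(need %in% names(subjects))) {
    abort(sprintf("`subjects` must have columns %s.", paste(need, collapse = ", ")))
  }
  if (any(subjects$gamma < 0 | subjects$gamma > 1)) {
    abort("Ground-truth `gamma` must lie in [0, 1].")
  }
  rng <- range(ild_set)
  for (i in seq_len(nrow(subjects))) {
    p <- predict_probit(rng, subjects$alpha[i], subjects$beta[i],
                        subjects$gamma[i], subjects$delta[i])
    if (any(p < 0 | p > 1)) {
      abort(sprintf(
        "Ground truth for subject %s at %g pps predicts probabilities outside [0, 1] over the ILD range.",
        subjects$subject[i], subjects$pps[i]
      ))
    }
  }
  invisible(subjects)
}

# balanced randomized block allocation of ILDs for one session
allocate_ilds <- function(ild_set, n_trials) {
  n_blocks <- n_trials %/% length(ild_set)
  rem <- n_trials %% length(ild_set)
  ilds <- c(
    unlist(lapply(seq_len(n_blocks), function(b) sample(ild_set))),
    if (rem > 0) sample(ild_set, rem, replace = FALSE)
  )
  ilds
}

# simulate one psychometric curve (one subject x pulse rate) with its own
# derived RNG stream; `p_rule` maps (ild, p_truth) -> possibly modified p
simulate_curve <- function(row, design, abl_db, p_rule = NULL) {
  seed <- derive_seed(design$seed, row$subject, format(row$pps))
  withr::with_seed(seed, {
    recs <- lapply(seq_len(design$n_sessions), function(s) {
      ild <- allocate_ilds(design$ild_set, design$trials_per_session)
      p <- predict_probit(ild, row$alpha, row$beta, row$gamma, row$delta)
      if (!is.null(p_rule)) p <- p_rule(ild, p)
      u <- runif(length(ild))
      resp <- ifelse(u < p, "right", "left")
      correct <- (resp == "right" & ild > 0) | (resp == "left" & ild < 0)
      if (any(ild == 0)) {
        correct[ild == 0] <- runif(sum(ild == 0)) < 0.5
      }
      tibble(
        subject = row$subject, session = s, pps = row$pps,
        ild_db = ild, abl_db = abl_db,
        response = resp, correct = correct, truth_p_right = p
      )
    })
    dplyr::bind_rows(recs)
  })
}

#' Simulate trial-level 2AFC lateralization data
#'
#' Draws one Bernoulli response per trial from each subject's ground-truth
#' probit-with-lapse psychometric function, under the given session design.
#' Each (subject, pulse rate) cell uses its own pseudorandom stream derived
#' from the design's master seed by a stable string hash, so the same seed
#' always reproduces the same records and adding subjects leaves existing
#' subjects' data untouched.
#'
#' @param subjects A truth table as returned by [virtual_subject()] /
#'   [make_cohort()]: one row per (subject, pps).
#' @param design A [session_design()].
#' @return A tibble of trial records: `subject`, `session`, `pps`, `ild_db`,
#'   `abl_db`, `response` (`"left"`/`"right"`), `correct`, `truth_p_right`.
#'   Positive ILD means right-louder, so `correct` is true when the response
#'   matches the sign of the ILD (fair coin at ILD = 0).
#' @examples
#' subj <- virtual_subject("r1", alpha = 0.5, gamma = 0.05)
#' d <- session_design(trials_per_session = 28, n_sessions = 1, seed = 42)
#' simulate_trials(subj, d)
#' @export
simulate_trials <- function(subjects, design) {
  stopifnot(inherits(design, "session_design"))
  validate_truth(subjects, design$ild_set)
  cells <- subjects |> dplyr::filter(.data$pps %in% design$pulse_rates)
  if (nrow(cells) == 0) {
    abort("No (subject, pps) rows match the design's `pulse_rates`.")
  }
  purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    simulate_curve(cells[i, ], design, design$abl_db)
  })
}

#' Simulate the monaural-audibility control condition
#'
#' Re-simulates trials at average binaural levels placed relative to each
#' subject's audibility threshold. Whenever the quieter ear's level
#' (`abl - |ild|/2`) falls below the subject's threshold, the binaural level
#' comparison is no longer available and the response probability collapses
#' to the guessing mixture `0.5 + delta`; other trials are unchanged. With
#' the same design seed, trials whose probability is unmodified are identical
#' to the [simulate_trials()] output, so the control is directly comparable.
#'
#' @inheritParams simulate_trials
#' @param abl_offsets ABLs to test, expressed in dB relative to each
#'   subject's `threshold_db` (e.g. `c(0, 10)` for at-threshold and
#'   comfortably suprathreshold).
#' @return Trial records as in [simulate_trials()], with an extra column
#'   `abl_offset_db`.
#' @export
simulate_audibility_control <- function(subjects, design, abl_offsets) {
  stopifnot(inherits(design, "session_design"))
  validate_truth(subjects, design$ild_set)
  if (any(!is.finite(subjects$threshold_db))) {
    abort("Every subject needs a finite `threshold_db` for the audibility control.")
  }
  purrr::map_dfr(seq_len(nrow(subjects)), function(i) {
    row <- subjects[i, ]
    purrr::map_dfr(abl_offsets, function(off) {
      abl <- row$threshold_db + off
      rule <- function(ild, p) {
        sub <- (abl - abs(ild) / 2) < row$threshold_db
        p[sub] <- 0.5 + row$delta
        p
      }
      simulate_curve(row, design, abl, p_rule = rule) |>
        dplyr::mutate(abl_offset_db = off)
    })
  })
}

#' Distribution specification for a synthetic cohort
#'
#' Parameter distributions from which [make_cohort()] draws each virtual
#' subject's ground truth at the reference rate of 900 pps. The defaults are
#' calibrated so the implied cohort medians sit near those observed in real
#' bilaterally implanted rats (median JND ~1.7 dB, median slope ~15 %/dB at
#' 900 pps): `alpha` log-normal with median `alpha_median`, `beta` centred
#' Gaussian, `gamma` Beta-distributed (mostly small lapse rates), `delta`
#' a small centred Gaussian clamped into the interval keeping all predicted
#' probabilities inside `[0, 1]`.
#'
#' @param alpha_median Median ILD sensitivity (probit units per dB) at 900 pps.
#' @param alpha_sdlog Log-scale SD of `alpha`.
#' @param beta_sd SD of the ear bias.
#' @param gamma_shape1,gamma_shape2 Beta shape parameters of the lapse rate.
#' @param delta_sd SD of the spout bias before clamping.
#' @return A `cohort_spec` list.
#' @export
cohort_param_spec <- function(alpha_median = 0.42, alpha_sdlog = 0.40,
                              beta_sd = 0.35, gamma_shape1 = 1.5,
                              gamma_shape2 = 20, delta_sd = 0.02) {
  stopifnot(alpha_median > 0, alpha_sdlog >= 0, beta_sd >= 0,
            gamma_shape1 > 0, gamma_shape2 > 0, delta_sd >= 0)
  structure(
    list(alpha_median = alpha_median, alpha_sdlog = alpha_sdlog,
         beta_sd = beta_sd, gamma_shape1 = gamma_shape1,
         gamma_shape2 = gamma_shape2, delta_sd = delta_sd),
    class = "cohort_spec"
  )
}

# relative true JND as a function of pulse rate, normalized to 1 at 900 pps;
# linear in log10(pps), calibrated so the 2400:300 pps mean-JND ratio is ~1.7
rate_jnd_factor <- function(pps) {
  pmax(-0.6715 + 0.5657 * log10(pps), 0.2)
}

#' Generate a reproducible synthetic cohort
#'
#' Draws `n_subjects` virtual subjects from a [cohort_param_spec()]. Each
#' subject receives one truth row per requested pulse rate; sensitivity
#' declines with pulse rate (the true JND scales linearly in `log10(pps)`,
#' normalized to the subject's value at 900 pps), while bias and lapse
#' parameters are shared across rates. The spout bias is clamped into the
#' widest interval keeping all predicted probabilities inside `[0, 1]` over
#' ILDs up to +/-6 dB.
#'
#' @param n_subjects Number of subjects (0 gives an empty cohort).
#' @param pulse_rates Pulse rates at which each subject has a curve.
#' @param spec A [cohort_param_spec()].
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param threshold_db Audibility threshold assigned to every subject
#'   (for the control simulation).
#' @return A truth tibble, one row per (subject, pps): columns as in
#'   [virtual_subject()].
#' @export
make_cohort <- function(n_subjects = 24, pulse_rates = 900,
                        spec = cohort_param_spec(), seed = 1L,
                        threshold_db = 0) {
  stopifnot(inherits(spec, "cohort_spec"), n_subjects >= 0)
  if (n_subjects == 0) {
    return(virtual_subject(character(0), numeric(0), numeric(0))[0, ])
  }
  withr::with_seed(as.integer(seed), {
    ids <- sprintf("S%02d", seq_len(n_subjects))
    alpha900 <- exp(log(spec$alpha_median) +
                      stats::rnorm(n_subjects, 0, spec$alpha_sdlog))
    beta <- stats::rnorm(n_subjects, 0, spec$beta_sd)
    gamma <- stats::rbeta(n_subjects, spec$gamma_shape1, spec$gamma_shape2)
    delta <- stats::rnorm(n_subjects, 0, spec$delta_sd)

    purrr::map_dfr(seq_len(n_subjects), function(i) {
      purrr::map_dfr(pulse_rates, function(r) {
        a <- alpha900[i] * rate_jnd_factor(900) / rate_jnd_factor(r)
        # widest delta interval keeping predictions in [0,1] at ILD = +/-6
        p_lo <- pnorm(-6 * abs(a) + beta[i]) * (1 - gamma[i]) + gamma[i] / 2
        p_hi <- pnorm(6 * abs(a) + beta[i]) * (1 - gamma[i]) + gamma[i] / 2
        d <- min(max(delta[i], -p_lo + 1e-6), 1 - p_hi - 1e-6)
        virtual_subject(ids[i], pps = r, alpha = a, beta = beta[i],
                        gamma = gamma[i], delta = d,
                        threshold_db = threshold_db)
      })
    })
  })
}
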