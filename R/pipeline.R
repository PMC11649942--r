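#' Configuration of an end-to-end analysis run
#'
#' Bundles every tunable of the simulate -> fit -> select -> metrics ->
#' regression pipeline into one serializable object. A run is fully
#' determined by its config: the single master seed drives every stage
#' stream, and the config is embedded in the run's artifacts.
#'
#' @param seed Master seed (integer).
#' @param n_subjects Cohort size.
#' @param pulse_rates Pulse rates tested (pps).
#' @param trials_per_session,n_sessions,ild_set,abl_db Session design, see
#'   [session_design()].
#' @param alpha_level Significance level of the deviance model-selection
#'   tests.
#' @param lapse_corrected JND convention flag, see [jnd()].
#' @param log_base Base for the rate regression's log(pps).
#' @param cohort_spec A [cohort_param_spec()].
#' @param figures Whether to render figure files.
#' @param out_dir Output directory for [run_pipeline()].
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n_subjects = 24, pulse_rates = 900,
                       trials_per_session = 200, n_sessions = 4,
                       ild_set = c(-(6:1), -0.5, 0.5, 1:6), abl_db = 10,
                       alpha_level = 0.05, lapse_corrected = FALSE,
                       log_base = 10, cohort_spec = cohort_param_spec(),
                       figures = TRUE, out_dir = "ildsense-run") {
  structure(
    list(
      seed = as.integer(seed), n_subjects = n_subjects,
      pulse_rates = pulse_rates, trials_per_session = trials_per_session,
      n_sessions = n_sessions, ild_set = ild_set, abl_db = abl_db,
      alpha_level = alpha_level, lapse_corrected = lapse_corrected,
      log_base = log_base, cohort_spec = cohort_spec,
      figures = figures, out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Read or write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_run_config()] returns a `run_config`;
#'   [write_run_config()] returns the path invisibly.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- do.call(cohort_param_spec, y$cohort_spec %||% list())
  y$cohort_spec <- NULL
  do.call(run_config, c(y, list(cohort_spec = spec)))
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  y <- unclass(config)
  y$cohort_spec <- unclass(y$cohort_spec)
  # the output location is a runtime detail, not an analysis parameter;
  # leaving it out keeps bundles hash-identical wherever they are written
  y$out_dir <- NULL
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write and read trial records as tidy CSV
#'
#' One row per trial with columns
#' `subject,session,pps,ild_db,abl_db,response,correct` (UTF-8, header
#' mandatory, decimal point). Reading normalizes response labels (case and
#' surrounding whitespace; `"r"`/`"right"` and `"l"`/`"left"` accepted) and
#' reports malformed rows with their line numbers.
#'
#' @param trials A trial tibble ([simulate_trials()] output or compatible).
#' @param path CSV path.
#' @return `write_trials()`: the path, invisibly. `read_trials()`: a trial
#'   tibble.
#' @export
write_trials <- function(trials, path) {
  cols <- c("subject", "session", "pps", "ild_db", "abl_db", "response", "correct")
  missing <- setdiff(cols, names(trials))
  if (length(missing) > 0) {
    abort(sprintf("Trial table lacks columns: %s.", paste(missing, collapse = ", ")))
  }
  readr::write_csv(trials[cols], path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  # readr's own parse warnings are redundant: problems() is inspected below
  # and malformed rows are reported with line numbers
  d <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      subject = readr::col_character(),
      session = readr::col_integer(),
      pps = readr::col_double(),
      ild_db = readr::col_double(),
      abl_db = readr::col_double(),
      response = readr::col_character(),
      correct = readr::col_logical()
    )
  ))
  need <- c("subject", "session", "pps", "ild_db", "abl_db", "response", "correct")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0) {
    abort(sprintf("Trial CSV is missing columns: %s.", paste(missing, collapse = ", ")))
  }
  if (nrow(d) == 0) abort(sprintf("Trial file %s contains no trials.", path))
  prob <- readr::problems(d)
  if (nrow(prob) > 0) {
    abort(sprintf(
      "Malformed trial rows in %s at line(s) %s.",
      path, paste(unique(prob$row + 1), collapse = ", ")
    ))
  }
  resp <- tolower(trimws(d$response))
  resp[resp == "r"] <- "right"
  resp[resp == "l"] <- "left"
  bad <- which(!resp %in% c("left", "right"))
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown response label(s) %s at line(s) %s of %s.",
      paste(unique(d$response[bad]), collapse = ", "),
      paste(bad + 1, collapse = ", "), path
    ))
  }
  bad_ild <- which(!is.finite(d$ild_db))
  if (length(bad_ild) > 0) {
    abort(sprintf("Non-numeric ILD at line(s) %s of %s.",
                  paste(bad_ild + 1, collapse = ", "), path))
  }
  d$response <- resp
  as_tibble(d)
}

# serialize one curve's fits + selection into a plain list for JSON
fit_report <- function(selection, subject, pps) {
  list(
    subject = subject, pps = pps,
    selected_model = selection$model,
    fits = lapply(selection$fits, function(f) {
      list(model = f$model, params = f$params, loglik = f$loglik,
           n_params = f$n_params, n_trials = f$n_trials,
           converged = f$converged, n_restarts_used = f$n_restarts_used)
    }),
    deviance_tests = selection$tests
  )
}

run_stage <- function(stage, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
          parent = e)
  })
  message(sprintf("[ildsense] %s: %.2f s", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, writes the trial table, fits and selects psychometric
#' models per (subject, pulse rate), extracts sensitivity metrics, summarizes
#' the cohort, regresses sensitivity on log pulse rate when two or more rates
#' are present, renders figures, and writes a manifest with an MD5 content
#' hash per artifact. Identical configs (including the seed) produce
#' hash-identical artifact bundles; figures are pure views regenerable from
#' the CSV/JSON artifacts.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`cohort`, `trials`,
#'   `fits`, `sensitivity`, `cohort_summary`, `regressions`) and `manifest`
#'   (tibble of artifact paths and hashes).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)
  artifacts <- character(0)
  emit <- function(f) { artifacts <<- c(artifacts, path(f)); path(f) }

  write_run_config(config, emit("config.yaml"))

  cohort <- run_stage("simulate cohort", make_cohort(
    n_subjects = config$n_subjects, pulse_rates = config$pulse_rates,
    spec = config$cohort_spec, seed = derive_seed(config$seed, "cohort")
  ))
  design <- session_design(
    ild_set = config$ild_set, trials_per_session = config$trials_per_session,
    n_sessions = config$n_sessions, pulse_rates = config$pulse_rates,
    abl_db = config$abl_db, seed = derive_seed(config$seed, "trials")
  )
  trials <- run_stage("simulate trials", simulate_trials(cohort, design))
  write_trials(trials, emit("trials.csv"))
  readr::write_csv(cohort, emit("cohort_truth.csv"))

  fits <- run_stage("fit models", fit_curves(trials, alpha_level = config$alpha_level))
  reports <- purrr::map(seq_len(nrow(fits)), function(i) {
    fit_report(fits$selection[[i]], fits$subject[i], fits$pps[i])
  })
  jsonlite::write_json(reports, emit("fits.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")

  sens <- run_stage("sensitivity metrics",
                    ild_sensitivity(fits, lapse_corrected = config$lapse_corrected))
  readr::write_csv(sens, emit("sensitivity.csv"))

  cohort_summary <- summarize_cohort(sens)
  cfg_plain <- unclass(config)
  cfg_plain$cohort_spec <- unclass(cfg_plain$cohort_spec)
  cfg_plain$out_dir <- NULL
  jsonlite::write_json(
    list(config = cfg_plain, summary = cohort_summary),
    emit("cohort_summary.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows"
  )

  regressions <- NULL
  if (length(unique(sens$pps)) >= 2) {
    regressions <- run_stage("rate regression", list(
      slope = regress_log_rate(sens, "slope", log_base = config$log_base),
      jnd = regress_log_rate(sens, "jnd", log_base = config$log_base)
    ))
    jsonlite::write_json(
      list(slope = glance(regressions$slope), jnd = glance(regressions$jnd),
           means = mean_by_rate(sens)),
      emit("rate_regression.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows"
    )
  }

  if (isTRUE(config$figures)) {
    run_stage("figures", {
      ggplot2::ggsave(emit("fig_psychometric.png"),
                      plot_psychometric(fits), width = 10, height = 8, dpi = 120)
      ggplot2::ggsave(emit("fig_cohort.png"),
                      plot_cohort(sens), width = 7, height = 4, dpi = 120)
      if (!is.null(regressions)) {
        ggplot2::ggsave(emit("fig_rates.png"),
                        plot_rate_sensitivity(sens, log_base = config$log_base),
                        width = 8, height = 4, dpi = 120)
      }
    })
  }

  manifest <- tibble(
    file = basename(artifacts),
    bytes = file.size(artifacts),
    md5 = unname(tools::md5sum(artifacts))
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")

  invisible(list(
    cohort = cohort, trials = trials, fits = fits, sensitivity = sens,
    cohort_summary = cohort_summary, regressions = regressions,
    manifest = manifest
  ))
}
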