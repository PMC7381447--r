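.config_defaults <- function() {
  list(
    seed = 1L,
    output_dir = "searchddm-output",
    input_csv = NULL,
    design = list(n_blocks = 8L, trials_per_block = 32L,
                  include_practice = TRUE, min_hue_separation = 30,
                  rt_timeout = 2000),
    generative = list(n_participants = 30L, model_id = "MIT",
                      drift_rate = 0.0011, noise_level = 0.03,
                      drift_rate_change = 8e-04, cv = 0.2, cv_delta = 0,
                      congruency_offset = 0),
    preprocessing = list(min_rt = 200, max_rt = 2000, min_accuracy = 0.7),
    fitting = list(grid_n = 7L, nm_maxit = 60L, n_coarse = 13L,
                   n_fine = 11L, matching = "conditional"),
    analysis = list(min_cell_size = 10L, prior_scale = sqrt(2) / 2)
  )
}

check_keys <- function(given, allowed, where) {
  extra <- setdiff(names(given), allowed)
  if (length(extra) > 0)
    stop_searchddm(paste0("unknown config key", if (length(extra) > 1) "s",
                          " in ", where, ": ",
                          paste(extra, collapse = ", ")),
                   "searchddm_validation_error")
}

#' Build and validate a run configuration
#'
#' Merges user settings over the package defaults and validates them
#' before any stage runs. Accepts either a named list or the path of a
#' YAML file with the same structure (blocks `design`, `generative`,
#' `preprocessing`, `fitting`, `analysis`, plus `seed`, `output_dir` and
#' optional `input_csv`). Unknown keys are rejected.
#'
#' @param config Named list or YAML file path; `NULL` gives the defaults.
#' @return A validated config list of class `run_config`.
#' @export
run_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  if (!is.list(config))
    stop_searchddm("config must be a list or a YAML path",
                   "searchddm_validation_error")
  defs <- .config_defaults()
  check_keys(config, names(defs), "config")
  for (block in c("design", "generative", "preprocessing", "fitting",
                  "analysis"))
    if (!is.null(config[[block]]))
      check_keys(config[[block]], names(defs[[block]]), block)
  cfg <- modifyList(defs, config)
  # validate eagerly: constructors raise parameter errors
  design_spec(cfg$design$n_blocks, cfg$design$trials_per_block,
              cfg$design$include_practice, cfg$design$min_hue_separation,
              cfg$design$rt_timeout)
  if (is.null(cfg$input_csv)) {
    if (cfg$generative$n_participants < 1)
      stop_searchddm("generative$n_participants must be >= 1",
                     "searchddm_validation_error")
    cohort_params(cfg$generative$drift_rate, cfg$generative$noise_level,
                  cfg$generative$drift_rate_change, cfg$generative$cv,
                  cfg$generative$cv_delta)
    if (!cfg$generative$model_id %in% c("MIT", "SIT"))
      stop_searchddm("generative$model_id must be MIT or SIT",
                     "searchddm_validation_error")
  }
  if (cfg$preprocessing$min_rt >= cfg$preprocessing$max_rt)
    stop_searchddm("preprocessing: min_rt must be below max_rt",
                   "searchddm_validation_error")
  if (cfg$analysis$prior_scale <= 0)
    stop_searchddm("analysis$prior_scale must be positive",
                   "searchddm_validation_error")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Z-score a participant's correct RTs
#'
#' @param x Numeric RT vector with at least 2 values and nonzero spread.
#' @return `(x - mean(x)) / sd(x)`.
#' @export
zscore_correct_rts <- function(x) {
  if (length(x) < 2)
    stop_searchddm("need at least 2 RTs to z-score",
                   "searchddm_analysis_error")
  s <- sd(x)
  if (s == 0)
    stop_searchddm("zero variance RT vector", "searchddm_analysis_error")
  (x - mean(x)) / s
}

# Simulate the per-condition trial counts of one participant under a
# fitted model and return pooled z-scored correct RTs plus per-condition
# accuracy (the model-based panels of the report).
simulate_report_panel <- function(trials, model, params) {
  drifts <- effective_drift(model, trials$condition, params$drift_rate)
  sim <- simulate_trials(params, drifts)
  acc <- tapply(sim$correct, factor(trials$condition, .conditions), mean)
  z <- zscore_correct_rts(sim$rt[sim$correct])
  cond <- trials$condition[sim$correct]
  list(z = z, condition = cond, accuracy = acc)
}

report_surfaces <- function(trials, fits, seed) {
  ok <- fits[!fits$mit_failed & !fits$sit_failed, , drop = FALSE]
  obs_z <- list(); mit_z <- list(); sit_z <- list()
  obs_cond <- list(); mit_cond <- list(); sit_cond <- list()
  acc <- list()
  for (i in seq_len(nrow(ok))) {
    id <- ok$participant_id[i]
    tr <- trials[trials$participant_id == id, , drop = FALSE]
    obs_z[[i]] <- zscore_correct_rts(tr$rt[tr$correct])
    obs_cond[[i]] <- tr$condition[tr$correct]
    params <- ddm_params(ok$drift_rate[i], ok$noise_level[i])
    set.seed(seed + i)
    mit <- simulate_report_panel(tr, template_model("MIT", ok$delta_mit[i]),
                                 params)
    sit <- simulate_report_panel(tr, template_model("SIT", ok$delta_sit[i]),
                                 params)
    mit_z[[i]] <- mit$z; mit_cond[[i]] <- mit$condition
    sit_z[[i]] <- sit$z; sit_cond[[i]] <- sit$condition
    acc[[i]] <- data.frame(participant_id = id, condition = .conditions,
                           observed = as.numeric(
                             tapply(tr$correct,
                                    factor(tr$condition, .conditions),
                                    mean)),
                           mit = as.numeric(mit$accuracy),
                           sit = as.numeric(sit$accuracy))
  }
  list(zscores = data.frame(
         source = rep(c("observed", "MIT", "SIT"),
                      times = c(length(unlist(obs_z)),
                                length(unlist(mit_z)),
                                length(unlist(sit_z)))),
         condition = c(unlist(obs_cond), unlist(mit_cond),
                       unlist(sit_cond)),
         z = c(unlist(obs_z), unlist(mit_z), unlist(sit_z))),
       accuracy = do.call(rbind, acc))
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate (or load) -> preprocess -> summarize -> fit ->
#' compare -> report under a single master seed, writing every stage's
#' output (trial CSV, exclusion report, condition summaries, fit table,
#' model and width comparisons, z-scored RT / accuracy tables, and a copy
#' of the configuration) into the configured output directory.
#'
#' @param config A [run_config()], or anything it accepts.
#' @param stages Character vector of stages to run (in pipeline order);
#'   default all. Fitting-dependent stages require `"fit"`.
#' @return A list of class `analysis_report` with the stage results.
#' @export
run_pipeline <- function(config = NULL,
                         stages = c("generate", "preprocess", "summarize",
                                    "fit", "compare", "report")) {
  cfg <- run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(cfg$output_dir, "config.yaml"))
  report <- list(config = cfg)

  if (!is.null(cfg$input_csv)) {
    trials <- read_trials(cfg$input_csv)
  } else {
    design <- design_spec(cfg$design$n_blocks, cfg$design$trials_per_block,
                          cfg$design$include_practice,
                          cfg$design$min_hue_separation,
                          cfg$design$rt_timeout)
    cohort <- cohort_params(cfg$generative$drift_rate,
                            cfg$generative$noise_level,
                            cfg$generative$drift_rate_change,
                            cfg$generative$cv, cfg$generative$cv_delta)
    trials <- simulate_cohort(cfg$generative$n_participants, design,
                              cfg$generative$model_id, cohort,
                              master_seed = cfg$seed,
                              congruency_offset =
                                cfg$generative$congruency_offset)
    write_trials(trials, file.path(cfg$output_dir, "trials.csv"))
    write.csv(attr(trials, "participants"),
              file.path(cfg$output_dir, "participants.csv"),
              row.names = FALSE)
  }

  pp <- preprocess(trials, cfg$preprocessing$min_rt,
                   cfg$preprocessing$max_rt,
                   cfg$preprocessing$min_accuracy)
  report$exclusions <- pp$report
  write_json(unclass(pp$report), file.path(cfg$output_dir,
                                           "exclusions.json"))

  if ("summarize" %in% stages) {
    report$summaries <- condition_summaries(pp$trials)
    write.csv(report$summaries$grand,
              file.path(cfg$output_dir, "condition_summaries.csv"),
              row.names = FALSE)
  }

  if ("fit" %in% stages) {
    fits <- fit_cohort(pp$trials, master_seed = cfg$seed,
                       grid_n = cfg$fitting$grid_n,
                       nm_maxit = cfg$fitting$nm_maxit,
                       matching = cfg$fitting$matching)
    report$fits <- fits
    write.csv(fits, file.path(cfg$output_dir, "fits.csv"),
              row.names = FALSE)
    write_json(fits, file.path(cfg$output_dir, "fits.json"))
    if ("compare" %in% stages) {
      cmp <- compare_models(fits, r = cfg$analysis$prior_scale)
      report$model_comparison <- cmp
      write_json(cmp[c("n_total", "n_excluded", "n", "t", "df", "p",
                       "bf10", "favored")],
                 file.path(cfg$output_dir, "model_comparison.json"))
      wc <- width_comparison(pp$trials,
                             min_n = cfg$analysis$min_cell_size,
                             r = cfg$analysis$prior_scale)
      report$width_comparison <- wc
      write_json(wc[c("n", "t", "df", "p", "bf01", "bf10", "direction")],
                 file.path(cfg$output_dir, "width_comparison.json"))
    }
    if ("report" %in% stages) {
      surf <- report_surfaces(pp$trials, fits, cfg$seed)
      report$surfaces <- surf
      write.csv(surf$zscores,
                file.path(cfg$output_dir, "zscored_rts.csv"),
                row.names = FALSE)
      write.csv(surf$accuracy,
                file.path(cfg$output_dir, "accuracy_by_condition.csv"),
                row.names = FALSE)
    }
  }
  structure(report, class = "analysis_report")
}
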