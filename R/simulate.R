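#' Fill a trial table with simulated responses
#'
#' Simulates every trial of a table from the diffusion model under a
#' template model's drift schedule: the per-trial effective drift is drawn
#' from the model's condition schedule (deterministic for MIT, a 50/50
#' template mixture for SIT) and a response is accumulated to threshold.
#' An optional additive congruency offset (an extension, off by default;
#' the template schedules themselves ignore congruency) raises the drift on
#' congruent trials and lowers it on incongruent ones.
#'
#' @param table Trial table from [build_trial_table()] with missing
#'   responses.
#' @param model A [template_model()].
#' @param params A [ddm_params()] holding the participant's base drift and
#'   noise level.
#' @param congruency_offset Additive drift offset, applied with sign `+1`
#'   on congruent and `-1` on incongruent trials. Default 0.
#' @return The table with `rt` (ms) and `correct` filled.
#' @export
simulate_participant <- function(table, model, params,
                                 congruency_offset = 0) {
  stopifnot(inherits(model, "template_model"),
            inherits(params, "ddm_params"))
  if (!all(is.na(table$rt)))
    stop_searchddm("table already contains responses",
                   "searchddm_data_error")
  drifts <- effective_drift(model, table$condition, params$drift_rate)
  drifts <- drifts + ifelse(table$congruent, 1, -1) * congruency_offset
  sim <- simulate_trials(params, drifts)
  table$rt <- sim$rt
  table$correct <- sim$correct
  table
}

#' Between-participant parameter distribution for cohort simulation
#'
#' Participant-level diffusion parameters are drawn from log-normal
#' distributions centered (in the median) on the stated values with a
#' common coefficient of variation, mimicking stable individual
#' differences; the drift-rate change is shared unless `cv_delta > 0`.
#'
#' @param drift_rate Median base drift rate. Default 0.0011.
#' @param noise_level Median noise level. Default 0.03.
#' @param drift_rate_change Median drift-rate change. Default 8e-04.
#' @param cv Log-normal coefficient of variation for drift and noise.
#'   Default 0.2.
#' @param cv_delta Coefficient of variation for the drift-rate change.
#'   Default 0.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(drift_rate = 0.0011, noise_level = 0.03,
                          drift_rate_change = 8e-04, cv = 0.2,
                          cv_delta = 0) {
  stopifnot(drift_rate > 0, noise_level > 0, drift_rate_change >= 0,
            cv >= 0, cv_delta >= 0)
  structure(list(drift_rate = drift_rate, noise_level = noise_level,
                 drift_rate_change = drift_rate_change, cv = cv,
                 cv_delta = cv_delta),
            class = "cohort_params")
}

draw_participant_params <- function(cohort) {
  lnorm1 <- function(m, cv) if (cv > 0) rlnorm(1, log(m), cv) else m
  list(drift_rate = lnorm1(cohort$drift_rate, cohort$cv),
       noise_level = lnorm1(cohort$noise_level, cohort$cv),
       drift_rate_change = if (cohort$drift_rate_change > 0)
         lnorm1(cohort$drift_rate_change, cohort$cv_delta) else 0)
}

#' Simulate a cohort of synthetic participants
#'
#' Generates `n_participants` trial tables and fills them from the chosen
#' generative template model, drawing each participant's diffusion
#' parameters from `cohort`. Reproducibility: participant `i` runs under
#' the child seed `master_seed + i` (sequential spawn), so cohorts are a
#' pure function of their arguments.
#'
#' @param n_participants Number of participants; `>= 1`.
#' @param design A [design_spec()].
#' @param model_id `"MIT"` or `"SIT"`.
#' @param cohort A [cohort_params()].
#' @param master_seed Integer master seed.
#' @param file Optional path; when given the trial table is also written as
#'   CSV via [write_trials()].
#' @param congruency_offset Passed to [simulate_participant()].
#' @return A data.frame of trial records for all participants, with the
#'   per-participant parameter draws attached as attribute
#'   `"participants"`.
#' @export
simulate_cohort <- function(n_participants, design, model_id, cohort,
                            master_seed = 1L, file = NULL,
                            congruency_offset = 0) {
  if (!is.numeric(n_participants) || n_participants < 1)
    stop_searchddm("n_participants must be >= 1", "searchddm_param_error")
  stopifnot(inherits(design, "design_spec"),
            inherits(cohort, "cohort_params"))
  out <- vector("list", n_participants)
  pars <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    set.seed(master_seed + i)
    pp <- draw_participant_params(cohort)
    model <- template_model(model_id, pp$drift_rate_change)
    params <- ddm_params(pp$drift_rate, pp$noise_level,
                         timeout = design$rt_timeout)
    pid <- sprintf("p%03d", i)
    tab <- build_trial_table(design, pid)
    out[[i]] <- simulate_participant(tab, model, params, congruency_offset)
    pars[[i]] <- data.frame(participant_id = pid, seed = master_seed + i,
                            drift_rate = pp$drift_rate,
                            noise_level = pp$noise_level,
                            drift_rate_change = pp$drift_rate_change)
  }
  trials <- do.call(rbind, out)
  attr(trials, "participants") <- do.call(rbind, pars)
  if (!is.null(file)) write_trials(trials, file)
  trials
}

#' Write a trial table as CSV
#'
#' Columns `participant_id, block, trial, is_practice, target_match,
#' distractor_match, congruent, condition, memory_hue_1, memory_hue_2,
#' rt_ms, correct`, with booleans encoded 0/1 and missing responses as
#' empty fields.
#'
#' @param trials Trial table.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trials <- function(trials, file) {
  out <- data.frame(participant_id = trials$participant_id,
                    block = trials$block,
                    trial = trials$trial,
                    is_practice = as.integer(trials$is_practice),
                    target_match = as.integer(trials$target_match),
                    distractor_match = as.integer(trials$distractor_match),
                    congruent = as.integer(trials$congruent),
                    condition = trials$condition,
                    memory_hue_1 = trials$memory_hue_1,
                    memory_hue_2 = trials$memory_hue_2,
                    rt_ms = trials$rt,
                    correct = as.integer(trials$correct))
  write.csv(out, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' Read a trial table written by [write_trials()]
#'
#' @param file CSV path.
#' @return A trial table data.frame with logical factors and integer `rt`.
#' @export
read_trials <- function(file) {
  raw <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("participant_id", "block", "trial", "is_practice",
            "target_match", "distractor_match", "congruent", "condition",
            "memory_hue_1", "memory_hue_2", "rt_ms", "correct")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0)
    stop_searchddm(paste("trial CSV lacks columns:",
                         paste(missing_cols, collapse = ", ")),
                   "searchddm_data_error")
  data.frame(participant_id = as.character(raw$participant_id),
             block = as.integer(raw$block),
             trial = as.integer(raw$trial),
             is_practice = raw$is_practice == 1,
             target_match = raw$target_match == 1,
             distractor_match = raw$distractor_match == 1,
             congruent = raw$congruent == 1,
             condition = raw$condition,
             memory_hue_1 = raw$memory_hue_1,
             memory_hue_2 = raw$memory_hue_2,
             rt = as.integer(raw$rt_ms),
             correct = ifelse(is.na(raw$correct), NA, raw$correct == 1))
}
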