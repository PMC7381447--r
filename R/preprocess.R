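#' Trial-level RT filter
#'
#' Drops practice trials, then excludes trials with RTs shorter than
#' `min_rt` or longer than `max_rt` (boundary values are kept: only
#' strictly shorter/longer trials are excluded).
#'
#' @param trials Trial table with responses.
#' @param min_rt,max_rt Bounds in ms. Defaults 200 and 2000.
#' @return A list with `trials` (kept rows) and `report`
#'   (`n_in`, `n_kept`, counted on test trials).
#' @export
filter_trials <- function(trials, min_rt = 200, max_rt = 2000) {
  test <- trials[!trials$is_practice, , drop = FALSE]
  if (any(is.na(test$rt)))
    stop_searchddm("missing rt on a test trial", "searchddm_data_error")
  kept <- test[test$rt >= min_rt & test$rt <= max_rt, , drop = FALSE]
  list(trials = kept,
       report = list(n_in = nrow(test), n_kept = nrow(kept)))
}

#' Participant-level accuracy filter
#'
#' Excludes participants whose overall search accuracy, computed on the
#' trials given (i.e. after the RT filter when called through
#' [preprocess()]), is below `min_accuracy`.
#'
#' @param trials RT-filtered trial table.
#' @param min_accuracy Exclusion threshold; participants at or above it are
#'   kept. Default 0.7.
#' @return A list with `trials`, and `report` holding participant counts
#'   and the per-participant accuracy table.
#' @export
exclude_participants <- function(trials, min_accuracy = 0.7) {
  if (any(is.na(trials$correct)))
    stop_searchddm("missing correctness on a test trial",
                   "searchddm_data_error")
  acc <- aggregate(correct ~ participant_id, data = trials, FUN = mean)
  names(acc)[2] <- "accuracy"
  keep_ids <- acc$participant_id[acc$accuracy >= min_accuracy]
  kept <- trials[trials$participant_id %in% keep_ids, , drop = FALSE]
  list(trials = kept,
       report = list(n_participants_in = nrow(acc),
                     n_participants_kept = length(keep_ids),
                     accuracy = acc))
}

#' Full exclusion pipeline
#'
#' Fixed order: drop practice trials, apply the RT filter, then the
#' participant accuracy filter (so accuracies are computed on RT-filtered
#' trials). Returns the kept trials together with a reconciled exclusion
#' report.
#'
#' @inheritParams filter_trials
#' @inheritParams exclude_participants
#' @return A list with `trials` and `report` (class `exclusion_report`):
#'   `n_trials_in`, `n_trials_kept`, `n_participants_in`,
#'   `n_participants_kept`, and the per-participant `accuracy` table.
#' @export
preprocess <- function(trials, min_rt = 200, max_rt = 2000,
                       min_accuracy = 0.7) {
  f <- filter_trials(trials, min_rt, max_rt)
  e <- exclude_participants(f$trials, min_accuracy)
  report <- structure(list(n_trials_in = f$report$n_in,
                           n_trials_kept = nrow(e$trials),
                           n_participants_in = e$report$n_participants_in,
                           n_participants_kept =
                             e$report$n_participants_kept,
                           accuracy = e$report$accuracy),
                      class = "exclusion_report")
  list(trials = e$trials, report = report)
}

#' Correct-trial RT vectors per participant and cell
#'
#' Only RTs of correct trials enter the distributional analyses. Returns
#' one row per participant x condition (x congruency when
#' `by_congruency`), with the RT vector as a list column and empty cells
#' flagged rather than fabricated.
#'
#' @param trials Filtered trial table.
#' @param by_congruency Split cells by orientation congruency too. Default
#'   `FALSE`.
#' @return A data.frame with columns `participant_id`, `condition`
#'   (optionally `congruent`), `n`, `empty`, and list column `rts`.
#' @export
correct_rt_view <- function(trials, by_congruency = FALSE) {
  cor <- trials[trials$correct, , drop = FALSE]
  grid <- expand.grid(participant_id = unique(trials$participant_id),
                      condition = .conditions,
                      congruent = if (by_congruency) c(FALSE, TRUE) else NA,
                      stringsAsFactors = FALSE)
  grid$rts <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- cor$participant_id == grid$participant_id[i] &
      cor$condition == grid$condition[i]
    if (by_congruency) sel <- sel & cor$congruent == grid$congruent[i]
    as.numeric(cor$rt[sel])
  })
  grid$n <- vapply(grid$rts, length, integer(1))
  grid$empty <- grid$n == 0
  if (!by_congruency) grid$congruent <- NULL
  grid
}

# Cousineau-Morey within-subject 95% CI half-widths per condition cell:
# subject means are removed (plus grand mean restored), the per-cell SD of
# the normalized scores is corrected by sqrt(C / (C - 1)).
morey_ci <- function(mat, level = 0.95) {
  n <- nrow(mat)
  C <- ncol(mat)
  norm <- mat - rowMeans(mat) + mean(mat)
  half <- apply(norm, 2, sd) / sqrt(n) * sqrt(C / (C - 1)) *
    qt(1 - (1 - level) / 2, df = n - 1)
  half
}

#' Condition summaries with within-subject confidence intervals
#'
#' Mean correct RT and accuracy per 2 x 2 x 2 design cell, per participant
#' and at the cohort level, with condition-specific within-subject 95%
#' confidence intervals (Cousineau-Morey normalization).
#'
#' @param trials Filtered trial table.
#' @return A list with `per_participant` (one row per participant x cell)
#'   and `grand` (one row per cell with means and CI half-widths
#'   `rt_ci_half`, `acc_ci_half`).
#' @export
condition_summaries <- function(trials) {
  trials$cell <- interaction(trials$condition, trials$congruent, drop = FALSE)
  per <- aggregate(cbind(accuracy = correct) ~ participant_id + condition +
                     congruent, data = trials, FUN = mean)
  rt_per <- aggregate(rt ~ participant_id + condition + congruent,
                      data = trials[trials$correct, , drop = FALSE],
                      FUN = mean)
  names(rt_per)[4] <- "mean_rt"
  per <- merge(per, rt_per, all.x = TRUE)
  grand <- aggregate(cbind(mean_rt, accuracy) ~ condition + congruent,
                     data = per, FUN = mean)
  # within-subject CIs require a complete participant x cell matrix
  ids <- unique(per$participant_id)
  cells <- paste(grand$condition, grand$congruent)
  to_mat <- function(value) {
    m <- matrix(NA_real_, nrow = length(ids), ncol = length(cells),
                dimnames = list(ids, cells))
    m[cbind(match(per$participant_id, ids),
            match(paste(per$condition, per$congruent), cells))] <-
      per[[value]]
    m
  }
  rt_mat <- to_mat("mean_rt")
  acc_mat <- to_mat("accuracy")
  if (length(ids) > 1 && !anyNA(rt_mat)) {
    grand$rt_ci_half <- morey_ci(rt_mat)[cells]
    grand$acc_ci_half <- morey_ci(acc_mat)[cells]
  } else {
    grand$rt_ci_half <- NA_real_
    grand$acc_ci_half <- NA_real_
  }
  list(per_participant = per, grand = grand)
}
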