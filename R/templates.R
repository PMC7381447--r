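#' Attentional-template model specification
#'
#' Encodes the two competing hypotheses as drift-rate schedules over the
#' four trial types. Under the Multiple-Item-Template (MIT) model both
#' memorized colors guide attention on every trial, so a matching target
#' always adds the drift-rate change and a matching distractor always
#' subtracts it (and the two cancel on both-match trials). Under the
#' Single-Item-Template (SIT) model only one memory item is the active
#' template on any given trial, so each match condition receives the
#' drift-rate change on a random 50% of trials; both-match trials are a
#' 50/50 mixture of facilitation and interference.
#'
#' @param model_id `"MIT"` or `"SIT"`.
#' @param drift_rate_change The single facilitation/interference parameter
#'   added to or subtracted from the base drift; `>= 0`.
#' @return An object of class `template_model`.
#' @export
template_model <- function(model_id = c("MIT", "SIT"), drift_rate_change) {
  model_id <- match.arg(model_id)
  if (!is.numeric(drift_rate_change) || length(drift_rate_change) != 1 ||
      drift_rate_change < 0)
    stop_searchddm("drift_rate_change must be a single number >= 0",
                   "searchddm_param_error")
  structure(list(model_id = model_id,
                 drift_rate_change = drift_rate_change),
            class = "template_model")
}

# The per-condition drift mixture: two component drifts and the probability
# of the first. MIT schedules are degenerate (p1 = 1).
drift_mixture <- function(spec, condition, base_drift) {
  stopifnot(inherits(spec, "template_model"))
  if (!condition %in% .conditions)
    stop_searchddm(paste0("unknown condition label: ", condition),
                   "searchddm_param_error")
  v <- base_drift
  d <- spec$drift_rate_change
  if (spec$model_id == "MIT") {
    d1 <- switch(condition,
                 NonColorMatch = v,
                 TargetColorMatch = v + d,
                 DistractorColorMatch = v - d,
                 BothColorMatch = v)
    list(drift1 = d1, drift2 = d1, p1 = 1)
  } else {
    switch(condition,
           NonColorMatch = list(drift1 = v, drift2 = v, p1 = 1),
           TargetColorMatch = list(drift1 = v + d, drift2 = v, p1 = 0.5),
           DistractorColorMatch = list(drift1 = v - d, drift2 = v, p1 = 0.5),
           BothColorMatch = list(drift1 = v + d, drift2 = v - d, p1 = 0.5))
  }
}

#' Per-trial effective drift under a template model
#'
#' Maps trial conditions to effective drift rates following the model's
#' schedule. MIT conditions are deterministic; SIT match conditions draw
#' the active template independently per trial (50/50), so repeated calls
#' consume random numbers. The result can be negative when the drift-rate
#' change exceeds the base drift.
#'
#' @param spec A [template_model()].
#' @param condition Character vector of trial-type labels (see
#'   [condition_levels()]).
#' @param base_drift Base drift rate; `> 0`.
#' @return Numeric vector of effective drifts, one per element of
#'   `condition`.
#' @export
effective_drift <- function(spec, condition, base_drift) {
  if (base_drift <= 0)
    stop_searchddm("base_drift must be positive", "searchddm_param_error")
  out <- numeric(length(condition))
  for (cond in unique(condition)) {
    mix <- drift_mixture(spec, cond, base_drift)
    idx <- which(condition == cond)
    if (mix$p1 >= 1) {
      out[idx] <- mix$drift1
    } else {
      pick <- runif(length(idx)) < mix$p1
      out[idx] <- ifelse(pick, mix$drift1, mix$drift2)
    }
  }
  out
}

#' Expected effective drift under a template model
#'
#' Expectation of [effective_drift()] over the model's per-trial mixture;
#' deterministic helper used in tests and diagnostics.
#'
#' @inheritParams effective_drift
#' @return Numeric vector of expected drifts.
#' @export
expected_drift <- function(spec, condition, base_drift) {
  if (base_drift <= 0)
    stop_searchddm("base_drift must be positive", "searchddm_param_error")
  vapply(condition, function(cond) {
    mix <- drift_mixture(spec, cond, base_drift)
    mix$p1 * mix$drift1 + (1 - mix$p1) * mix$drift2
  }, numeric(1), USE.NAMES = FALSE)
}
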