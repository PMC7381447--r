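#' Drift-diffusion simulator parameters
#'
#' Bundles the parameters of the two-boundary accumulator: the symmetric
#' threshold (fixed at 1 activation unit in the reference design), the base
#' drift rate (activation units per 1-ms sample, strictly positive), the
#' noise level (SD of the Gaussian increment added each sample), the timeout
#' (samples; a timed-out attempt is discarded and restarted), and the
#' attempt cap after which simulation is declared failed.
#'
#' @param drift_rate Base drift rate, activation units per sample; `> 0`.
#' @param noise_level SD of the per-sample Gaussian increment; `> 0`.
#' @param threshold Absorbing boundary at `+threshold` (correct) and
#'   `-threshold` (incorrect). Default 1.
#' @param timeout Maximum samples per attempt. Default 2000, matching the
#'   2000-ms response deadline (1 sample = 1 ms).
#' @param max_attempts Restart budget per response. Default 1000.
#' @return An object of class `ddm_params`.
#' @export
ddm_params <- function(drift_rate, noise_level, threshold = 1,
                       timeout = 2000, max_attempts = 1000) {
  if (!is.numeric(drift_rate) || length(drift_rate) != 1 || drift_rate <= 0)
    stop_searchddm("drift_rate must be a single positive number",
                   "searchddm_param_error")
  if (!is.numeric(noise_level) || length(noise_level) != 1 || noise_level <= 0)
    stop_searchddm("noise_level must be a single positive number",
                   "searchddm_param_error")
  if (threshold <= 0)
    stop_searchddm("threshold must be positive", "searchddm_param_error")
  if (timeout < 1 || max_attempts < 1)
    stop_searchddm("timeout and max_attempts must be >= 1",
                   "searchddm_param_error")
  structure(list(drift_rate = drift_rate, noise_level = noise_level,
                 threshold = threshold, timeout = as.integer(timeout),
                 max_attempts = as.integer(max_attempts)),
            class = "ddm_params")
}

# One substream seed per simulator call, drawn from R's RNG so that
# set.seed() fully determines the compiled simulator's output.
cpp_seed <- function() as.double(sample.int(2147483647L, 1L))

sim_failure <- function(what, index = NA_integer_) {
  stop(structure(
    class = c("searchddm_sim_failure", "searchddm_error", "error",
              "condition"),
    list(message = paste0("simulation failure: ", what,
                          " (attempt cap exhausted)"),
         call = NULL, index = index)))
}

#' Simulate responses from the two-boundary diffusion model
#'
#' Runs the discrete-time accumulator once per element of `effective_drift`:
#' starting from 0, each 1-ms sample adds the drift plus Gaussian noise;
#' absorption at `+threshold` yields a correct response with RT equal to the
#' sample index, absorption at `-threshold` an incorrect one. An attempt
#' that reaches the timeout is discarded and restarted from 0; exhausting
#' `max_attempts` raises a `searchddm_sim_failure` error.
#'
#' The effective drift may be any real number (a base drift minus a large
#' drift-rate change can be negative); only the base drift stored in
#' `params` is constrained positive.
#'
#' @param params A [ddm_params()] object.
#' @param effective_drift Numeric vector; one response is simulated per
#'   element.
#' @return A data.frame with integer `rt` (samples = ms, in `[1, timeout]`),
#'   logical `correct`, and `attempts` used.
#' @export
simulate_trials <- function(params, effective_drift = params$drift_rate) {
  stopifnot(inherits(params, "ddm_params"))
  res <- cpp_ddm_sim(as.numeric(effective_drift), params$noise_level,
                     params$threshold, params$timeout, params$max_attempts,
                     cpp_seed())
  if (isTRUE(res$failed))
    sim_failure("no boundary crossing within timeout", res$failed_index)
  data.frame(rt = res$rt, correct = res$correct, attempts = res$attempts)
}

#' Simulate a single response
#'
#' Convenience wrapper around [simulate_trials()] for one trial.
#'
#' @inheritParams simulate_trials
#' @return A one-row data.frame (`rt`, `correct`, `attempts`).
#' @export
simulate_trial <- function(params, effective_drift = params$drift_rate) {
  simulate_trials(params, effective_drift[1])
}

#' Simulate responses conditional on their correctness
#'
#' Rejection sampling per response: the accumulator is re-run, at the fixed
#' effective drift of that response, until the outcome has the required
#' correctness. Timed-out and wrong-category attempts both consume the
#' attempt budget; exhausting it raises `searchddm_sim_failure` (the
#' mechanism by which a model "fails to fit" when a required response
#' category is effectively unreachable, e.g. an incorrect response at a
#' strongly positive drift).
#'
#' Note the drift is held fixed across attempts. For mixture schedules
#' (SIT) the per-trial template draw therefore happens *before*
#' conditioning, in [effective_drift()], and is part of the trial's
#' identity.
#'
#' @inheritParams simulate_trials
#' @param required_correct Logical; the correctness every returned response
#'   must have.
#' @return A data.frame with `rt` and `attempts`, one row per element of
#'   `effective_drift`.
#' @export
simulate_conditional <- function(params, effective_drift, required_correct) {
  stopifnot(inherits(params, "ddm_params"), is.logical(required_correct),
            length(required_correct) == 1)
  res <- cpp_ddm_sim_conditional(as.numeric(effective_drift),
                                 required_correct, params$noise_level,
                                 params$threshold, params$timeout,
                                 params$max_attempts, cpp_seed())
  if (isTRUE(res$failed))
    sim_failure(sprintf("could not generate a %s response",
                        if (required_correct) "correct" else "incorrect"),
                res$failed_index)
  data.frame(rt = res$rt, attempts = res$attempts)
}

#' Continuum-limit absorption probability
#'
#' Closed-form probability that a Wiener process with the given drift and
#' infinitesimal SD, started midway between symmetric boundaries at
#' `+threshold` and `-threshold`, is absorbed at the upper (correct)
#' boundary: `1 / (1 + exp(-2 v A / s^2))`. Valid for the discrete
#' simulator in the small-step limit (`noise_level` well below the
#' threshold); used as an independent test oracle.
#'
#' @param effective_drift Drift rate v (any real).
#' @param noise_level Diffusion SD s; `> 0`.
#' @param threshold Boundary A; default 1.
#' @return Probability of a correct response.
#' @export
hit_probability_oracle <- function(effective_drift, noise_level,
                                   threshold = 1) {
  if (any(noise_level <= 0))
    stop_searchddm("noise_level must be positive", "searchddm_param_error")
  1 / (1 + exp(-2 * effective_drift * threshold / noise_level^2))
}

#' Continuum-limit mean decision time
#'
#' Closed-form unconditional mean first-passage time of the symmetric
#' two-boundary Wiener process: `(A / v) * tanh(v A / s^2)`, with the
#' drift-free limit `A^2 / s^2`. Same small-step caveat as
#' [hit_probability_oracle()].
#'
#' @inheritParams hit_probability_oracle
#' @return Expected decision time in samples.
#' @export
mean_decision_time_oracle <- function(effective_drift, noise_level,
                                      threshold = 1) {
  if (any(noise_level <= 0))
    stop_searchddm("noise_level must be positive", "searchddm_param_error")
  ifelse(effective_drift == 0,
         threshold^2 / noise_level^2,
         (threshold / effective_drift) *
           tanh(effective_drift * threshold / noise_level^2))
}
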