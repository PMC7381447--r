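# Sentinel objective value for candidates that cannot simulate the
# required responses (kept finite so simplex refinement stays stable).
.FIT_FAIL <- 1e15

#' Stage-1 rank ordering
#'
#' Orders a participant's RTs first by correctness (incorrect responses
#' first, a fixed documented convention), then ascending by value. Both
#' the observed and the simulated vector use the same ordering, so the
#' group order does not affect the RSS.
#'
#' @param rt Numeric RT vector.
#' @param correct Logical vector, same length.
#' @return Ordered numeric vector.
#' @export
rank_order_stage1 <- function(rt, correct) {
  c(sort(rt[!correct]), sort(rt[correct]))
}

#' Stage-2 rank ordering
#'
#' Nested ordering used when fitting the drift-rate change: correctness
#' (incorrect first), then trial type in the fixed order Non-, Target-,
#' Distractor-, Both-Color-Match, then ascending RT.
#'
#' @inheritParams rank_order_stage1
#' @param condition Trial-type labels.
#' @return Ordered numeric vector.
#' @export
rank_order_stage2 <- function(rt, correct, condition) {
  cond <- factor(condition, levels = .conditions)
  rt[order(correct, cond, rt)]
}

# Cell counts in the exact stage-2 nesting order (incorrect block first).
stage2_cell_counts <- function(correct, condition) {
  grid <- expand.grid(condition = .conditions, correct = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  grid$n <- vapply(seq_len(nrow(grid)), function(i) {
    sum(correct == grid$correct[i] & condition == grid$condition[i])
  }, integer(1))
  grid[, c("correct", "condition", "n")]
}

#' Residual sum of squares between ordered RT vectors
#'
#' @param real,simulated Equal-length numeric vectors, already rank
#'   ordered by the same scheme.
#' @return `sum((real - simulated)^2)` in squared ms.
#' @export
rss <- function(real, simulated) {
  if (length(real) != length(simulated))
    stop_searchddm("real and simulated vectors differ in length",
                   "searchddm_data_error")
  sum((real - simulated)^2)
}

#' Simulate responses matched to observed category counts
#'
#' Produces a simulated RT vector whose (correctness x trial type) cell
#' counts equal the observed ones exactly, by conditional (rejection)
#' simulation per cell, returned in the rank ordering of the matching
#' stage. Stage 1 (`model = NULL`) matches correctness counts only, at the
#' base drift; stage 2 matches correctness x condition cells under the
#' template model's drift schedule (for SIT, each response's template is
#' drawn before conditioning and held fixed, so a required category can be
#' unreachable — the failure-to-fit mechanism).
#'
#' @param params A [ddm_params()].
#' @param model A [template_model()], or `NULL` for the stage-1 base model.
#' @param cell_counts For stage 1, a named list or vector with elements
#'   `incorrect` and `correct`; for stage 2, the data.frame produced
#'   internally from the observed trials (`correct`, `condition`, `n`).
#' @param template_split How mixture cells assign templates to simulated
#'   responses: `"stratified"` (default) gives each template half of the
#'   cell, a variance-reduced estimator of the same 50/50 mixture;
#'   `"iid"` draws every assignment independently.
#' @param matching `"conditional"` (default) forces the simulated
#'   correctness counts to equal the observed ones per cell by rejection;
#'   `"unconditional"` simulates the observed number of trials freely, so
#'   the simulated correctness split is the model's own — the alternative
#'   reading of count matching, kept for sensitivity analysis.
#' @return Ordered numeric vector of simulated RTs; raises
#'   `searchddm_sim_failure` if a required response cannot be generated
#'   within the attempt cap.
#' @export
matched_simulation <- function(params, model, cell_counts,
                               template_split = c("stratified", "iid"),
                               matching = c("conditional",
                                            "unconditional")) {
  template_split <- match.arg(template_split)
  matching <- match.arg(matching)
  if (matching == "unconditional")
    return(unconditional_simulation(params, model, cell_counts,
                                    template_split))
  pool <- function(drift, n_cor, n_inc) {
    res <- cpp_ddm_sim_pool(drift, n_cor, n_inc, params$noise_level,
                            params$threshold, params$timeout,
                            params$max_attempts, cpp_seed())
    if (isTRUE(res$failed))
      sim_failure(sprintf("could not generate a %s response",
                          res$failed_category))
    list(correct = sort(res$correct_rt), incorrect = sort(res$incorrect_rt))
  }
  if (is.null(model)) {
    res <- pool(params$drift_rate, cell_counts[["correct"]],
                cell_counts[["incorrect"]])
    return(c(res$incorrect, res$correct))
  }
  stopifnot(is.data.frame(cell_counts))
  sims <- list()
  for (cond in .conditions) {
    mix <- drift_mixture(model, cond, params$drift_rate)
    n_inc <- cell_counts$n[!cell_counts$correct &
                             cell_counts$condition == cond]
    n_cor <- cell_counts$n[cell_counts$correct &
                             cell_counts$condition == cond]
    if (mix$p1 >= 1) {
      # one shared drift: pool-filling, identical in law to per-response
      # rejection at roughly half the cost
      res <- pool(mix$drift1, n_cor, n_inc)
      sims[[paste(FALSE, cond)]] <- res$incorrect
      sims[[paste(TRUE, cond)]] <- res$correct
    } else {
      # template mixture: each response's template is drawn first and
      # held fixed while conditioning on its correctness, so a required
      # category can be unreachable on a branch. Responses sharing a
      # branch are pooled (identical in law, cheaper). The default
      # stratified split assigns each template to half the responses
      # (odd remainders randomized), a variance-reduced estimator of the
      # same 50/50 mixture; "iid" draws every assignment independently.
      split_n <- function(n) {
        if (n == 0) return(0L)
        if (template_split == "stratified")
          n %/% 2L + (n %% 2L) * (runif(1) < mix$p1)
        else sum(runif(n) < mix$p1)
      }
      cor1 <- split_n(n_cor)
      inc1 <- split_n(n_inc)
      b1 <- pool(mix$drift1, cor1, inc1)
      b2 <- pool(mix$drift2, n_cor - cor1, n_inc - inc1)
      sims[[paste(FALSE, cond)]] <- sort(c(b1$incorrect, b2$incorrect))
      sims[[paste(TRUE, cond)]] <- sort(c(b1$correct, b2$correct))
    }
  }
  unlist(lapply(seq_len(nrow(cell_counts)), function(i) {
    sims[[paste(cell_counts$correct[i], cell_counts$condition[i])]]
  }), use.names = FALSE)
}

# The unconditional reading of count matching: simulate as many trials
# as observed (per condition for stage 2), let correctness fall where it
# may, and rank-order the result by the stage's scheme. Correctness
# counts then differ between data and simulation, so the RSS also
# penalizes error-rate mismatch.
unconditional_simulation <- function(params, model, cell_counts,
                                     template_split = "stratified") {
  if (is.null(model)) {
    n <- cell_counts[["correct"]] + cell_counts[["incorrect"]]
    sim <- simulate_trials(params, rep(params$drift_rate, n))
    return(rank_order_stage1(sim$rt, sim$correct))
  }
  stopifnot(is.data.frame(cell_counts))
  rts <- numeric(0); cors <- logical(0); conds <- character(0)
  for (cond in .conditions) {
    n <- sum(cell_counts$n[cell_counts$condition == cond])
    if (n == 0) next
    mix <- drift_mixture(model, cond, params$drift_rate)
    if (mix$p1 >= 1) {
      drifts <- rep(mix$drift1, n)
    } else if (template_split == "stratified") {
      n1 <- n %/% 2L + (n %% 2L) * (runif(1) < mix$p1)
      drifts <- c(rep(mix$drift1, n1), rep(mix$drift2, n - n1))
    } else {
      drifts <- ifelse(runif(n) < mix$p1, mix$drift1, mix$drift2)
    }
    sim <- simulate_trials(params, drifts)
    rts <- c(rts, sim$rt); cors <- c(cors, sim$correct)
    conds <- c(conds, rep(cond, n))
  }
  rank_order_stage2(rts, cors, conds)
}

# Evaluate an RSS objective under common random numbers: the RNG is reset
# to the same seed for every candidate, and simulation failure maps to the
# finite sentinel.
crn_objective <- function(seed, real_ordered, simulate_fn, n_rep = 1) {
  function(...) {
    vals <- vapply(seq_len(n_rep), function(k) {
      set.seed(seed + k - 1L)
      tryCatch(rss(real_ordered, simulate_fn(...)),
               searchddm_sim_failure = function(e) .FIT_FAIL)
    }, numeric(1))
    if (any(vals >= .FIT_FAIL)) .FIT_FAIL else mean(vals)
  }
}

#' Fit base drift rate and noise level (stage 1)
#'
#' Minimizes the stage-1 rank-ordered RSS between a participant's observed
#' RTs and correctness-matched simulated RTs over (drift rate, noise
#' level). The stochastic objective is evaluated with common random
#' numbers (one simulated replicate per evaluation, RNG reset per
#' candidate): a coarse log-spaced grid is followed by Nelder-Mead
#' refinement on the log scale. Candidates whose continuum-limit mean
#' decision time exceeds the timeout are rejected without simulation
#' (restart-until-valid cannot represent them).
#'
#' @param trials One participant's filtered trials (`rt`, `correct`).
#' @param seed Integer seed for the common-random-numbers objective.
#' @param drift_range,noise_range Search bounds (log-spaced grid).
#' @param grid_n Grid points per dimension. Default 7.
#' @param nm_maxit Nelder-Mead iteration budget. Default 60.
#' @param n_rep Simulated replicates averaged per objective evaluation.
#' @param matching Count-matching reading passed to
#'   [matched_simulation()].
#' @return A `ddm_fit` list: fitted `drift_rate`, `noise_level`, achieved
#'   `rss`, `fit_failed`, evaluation count `n_eval`, and `seed`.
#' @export
fit_base_params <- function(trials, seed = 1L,
                            drift_range = c(1e-4, 0.1),
                            noise_range = c(1e-3, 0.5),
                            grid_n = 7, nm_maxit = 60, n_rep = 1,
                            matching = "conditional") {
  if (sum(trials$correct) < 1)
    stop_searchddm("need at least one correct trial",
                   "searchddm_data_error")
  real <- rank_order_stage1(trials$rt, trials$correct)
  counts <- c(incorrect = sum(!trials$correct),
              correct = sum(trials$correct))
  timeout <- 2000L
  n_eval <- 0L
  obj_raw <- crn_objective(seed, real, function(v, s) {
    matched_simulation(ddm_params(v, s, timeout = timeout), NULL, counts,
                       matching = matching)
  }, n_rep = n_rep)
  obj <- function(v, s) {
    n_eval <<- n_eval + 1L
    if (v < drift_range[1] || v > drift_range[2] ||
        s < noise_range[1] || s > noise_range[2]) return(.FIT_FAIL)
    if (mean_decision_time_oracle(v, s) > timeout) return(.FIT_FAIL)
    obj_raw(v, s)
  }
  vs <- exp(seq(log(drift_range[1]), log(drift_range[2]), length.out = grid_n))
  ss <- exp(seq(log(noise_range[1]), log(noise_range[2]), length.out = grid_n))
  grid <- expand.grid(v = vs, s = ss)
  grid$val <- mapply(obj, grid$v, grid$s)
  best <- grid[which.min(grid$val), ]
  if (best$val >= .FIT_FAIL) {
    return(structure(list(participant_id = trials$participant_id[1],
                          stage = "base", model_id = "none",
                          drift_rate = NA_real_, noise_level = NA_real_,
                          drift_rate_change = NA_real_, rss = NA_real_,
                          fit_failed = TRUE, n_eval = n_eval, seed = seed),
                     class = "ddm_fit"))
  }
  opt <- optim(log(c(best$v, best$s)),
               function(p) obj(exp(p[1]), exp(p[2])),
               method = "Nelder-Mead",
               control = list(maxit = nm_maxit, reltol = 1e-3))
  if (opt$value <= best$val) {
    v_hat <- exp(opt$par[1]); s_hat <- exp(opt$par[2]); val <- opt$value
  } else {
    v_hat <- best$v; s_hat <- best$s; val <- best$val
  }
  structure(list(participant_id = trials$participant_id[1],
                 stage = "base", model_id = "none",
                 drift_rate = v_hat, noise_level = s_hat,
                 drift_rate_change = NA_real_, rss = val,
                 fit_failed = FALSE, n_eval = n_eval, seed = seed),
            class = "ddm_fit")
}

#' Fit the drift-rate change (stage 2)
#'
#' With the base drift rate and noise level held at their stage-1 values,
#' minimizes the stage-2 rank-ordered RSS over the drift-rate change
#' parameter of the given template model, on a coarse grid over
#' `[0, 2 * drift_rate]` followed by a fine grid around the best coarse
#' candidate (common random numbers throughout). A candidate for which a
#' required response category cannot be simulated scores the failure
#' sentinel; if every candidate fails, the fit is flagged `fit_failed` —
#' the model cannot generate the observed correctness pattern.
#'
#' @param trials One participant's filtered trials.
#' @param model_id `"MIT"` or `"SIT"`.
#' @param base_fit The participant's stage-1 `ddm_fit`.
#' @param seed Integer seed for the common-random-numbers objective.
#' @param n_coarse,n_fine Grid sizes. Defaults 13 and 11.
#' @param n_rep Simulated replicates averaged per objective evaluation.
#' @param matching Count-matching reading passed to
#'   [matched_simulation()].
#' @return A `ddm_fit` with `stage = "model"` and the fitted
#'   `drift_rate_change`.
#' @export
fit_drift_change <- function(trials, model_id, base_fit, seed = 1L,
                             n_coarse = 13, n_fine = 11, n_rep = 1,
                             matching = "conditional") {
  stopifnot(inherits(base_fit, "ddm_fit"))
  if (isTRUE(base_fit$fit_failed))
    stop_searchddm("stage-1 fit failed; cannot fit drift-rate change",
                   "searchddm_data_error")
  real <- rank_order_stage2(trials$rt, trials$correct, trials$condition)
  cells <- stage2_cell_counts(trials$correct, trials$condition)
  params <- ddm_params(base_fit$drift_rate, base_fit$noise_level)
  n_eval <- 0L
  obj_raw <- crn_objective(seed, real, function(delta) {
    matched_simulation(params, template_model(model_id, delta), cells,
                       matching = matching)
  }, n_rep = n_rep)
  obj <- function(delta) {
    n_eval <<- n_eval + 1L
    obj_raw(delta)
  }
  coarse <- seq(0, 2 * base_fit$drift_rate, length.out = n_coarse)
  val_c <- vapply(coarse, obj, numeric(1))
  i <- which.min(val_c)
  if (val_c[i] >= .FIT_FAIL) {
    return(structure(list(participant_id = trials$participant_id[1],
                          stage = "model", model_id = model_id,
                          drift_rate = base_fit$drift_rate,
                          noise_level = base_fit$noise_level,
                          drift_rate_change = NA_real_, rss = NA_real_,
                          fit_failed = TRUE, n_eval = n_eval, seed = seed),
                     class = "ddm_fit"))
  }
  step <- coarse[2] - coarse[1]
  lo <- max(0, coarse[i] - step)
  hi <- min(2 * base_fit$drift_rate, coarse[i] + step)
  fine <- seq(lo, hi, length.out = n_fine)
  val_f <- vapply(fine, obj, numeric(1))
  # quadratic-vertex refinement on the common-random-numbers profile:
  # the coupled objective is smooth enough locally that the parabola
  # through the fine grid locates the minimum below grid resolution
  okf <- val_f < .FIT_FAIL
  delta_hat <- fine[which.min(val_f)]
  if (sum(okf) >= 4) {
    qf <- stats::lm(val_f[okf] ~ stats::poly(fine[okf], 2, raw = TRUE))
    b <- stats::coef(qf)
    vert <- unname(-b[2] / (2 * b[3]))
    if (is.finite(vert) && b[3] > 0 && vert >= lo && vert <= hi)
      delta_hat <- vert
  }
  best_val <- obj(delta_hat)
  if (best_val >= .FIT_FAIL) {
    delta_hat <- fine[which.min(val_f)]
    best_val <- min(val_f)
  }
  failed <- best_val >= .FIT_FAIL
  structure(list(participant_id = trials$participant_id[1],
                 stage = "model", model_id = model_id,
                 drift_rate = base_fit$drift_rate,
                 noise_level = base_fit$noise_level,
                 drift_rate_change = if (failed) NA_real_ else delta_hat,
                 rss = if (failed) NA_real_ else best_val,
                 fit_failed = failed, n_eval = n_eval, seed = seed),
            class = "ddm_fit")
}

#' Fit every participant under both template models
#'
#' Runs the two-stage fit (base parameters, then the MIT and SIT
#' drift-rate change) for each participant. Per-participant seeds are
#' derived sequentially from the master seed (`master_seed + 101 * i +
#' stage offset`), so the whole cohort fit is reproducible.
#'
#' @param trials Filtered multi-participant trial table.
#' @param master_seed Integer master seed.
#' @param n_rep Objective replicates for the base stage (and, unless
#'   overridden, the model stage).
#' @param n_rep_model Objective replicates for the drift-rate-change
#'   stage; defaults to `n_rep`.
#' @param matching Count-matching reading passed to
#'   [matched_simulation()].
#' @param ... Passed on to [fit_base_params()].
#' @return A data.frame with one row per participant: fitted parameters,
#'   per-model RSS and failure flags.
#' @export
fit_cohort <- function(trials, master_seed = 1L, n_rep = 1,
                       n_rep_model = n_rep, matching = "conditional",
                       ...) {
  ids <- unique(trials$participant_id)
  rows <- lapply(seq_along(ids), function(i) {
    tr <- trials[trials$participant_id == ids[i], , drop = FALSE]
    s <- master_seed + 101L * i
    base <- fit_base_params(tr, seed = s + 1L, n_rep = n_rep,
                            matching = matching, ...)
    if (base$fit_failed) {
      return(data.frame(participant_id = ids[i],
                        drift_rate = NA_real_, noise_level = NA_real_,
                        base_rss = NA_real_, base_failed = TRUE,
                        delta_mit = NA_real_, rss_mit = NA_real_,
                        mit_failed = TRUE,
                        delta_sit = NA_real_, rss_sit = NA_real_,
                        sit_failed = TRUE))
    }
    # same stage-2 seed for both models: paired common random numbers,
    # so the simulation noise in rss_mit and rss_sit largely cancels in
    # the paired model comparison
    mit <- fit_drift_change(tr, "MIT", base, seed = s + 2L,
                            n_rep = n_rep_model, matching = matching)
    sit <- fit_drift_change(tr, "SIT", base, seed = s + 2L,
                            n_rep = n_rep_model, matching = matching)
    data.frame(participant_id = ids[i],
               drift_rate = base$drift_rate,
               noise_level = base$noise_level,
               base_rss = base$rss, base_failed = FALSE,
               delta_mit = mit$drift_rate_change, rss_mit = mit$rss,
               mit_failed = mit$fit_failed,
               delta_sit = sit$drift_rate_change, rss_sit = sit$rss,
               sit_failed = sit$fit_failed)
  })
  do.call(rbind, rows)
}

#' Compare MIT and SIT fit quality across a cohort
#'
#' Participants with a failed fit under either model are excluded; the
#' remaining per-participant RSS values are compared with a classical
#' two-sided paired t-test and a default (JZS) Bayes factor on the paired
#' differences `rss_sit - rss_mit`, so positive differences (and positive
#' t) favor MIT.
#'
#' @param fits Data.frame from [fit_cohort()].
#' @param r Cauchy prior scale for the Bayes factor. Default `sqrt(2)/2`.
#' @return A list of class `model_comparison`: `n_total`, `n_excluded`,
#'   `n`, `t`, `df`, `p`, `bf10`, `favored`, and the per-participant
#'   `table`.
#' @export
compare_models <- function(fits, r = sqrt(2) / 2) {
  ok <- !fits$mit_failed & !fits$sit_failed
  valid <- fits[ok, , drop = FALSE]
  if (nrow(valid) < 2)
    stop_searchddm("fewer than 2 participants with valid fits under both models",
                   "searchddm_analysis_error")
  d <- valid$rss_sit - valid$rss_mit
  if (sd(d) == 0) {
    tt <- list(statistic = 0, parameter = length(d) - 1, p.value = 1)
  } else {
    h <- t.test(d)
    tt <- list(statistic = unname(h$statistic),
               parameter = unname(h$parameter), p.value = h$p.value)
  }
  bf <- jzs_bf(tt$statistic, n = length(d), r = r)
  structure(list(n_total = nrow(fits), n_excluded = sum(!ok),
                 n = length(d), t = tt$statistic, df = tt$parameter,
                 p = tt$p.value, bf10 = bf$bf10,
                 favored = if (mean(d) >= 0) "MIT" else "SIT",
                 table = valid),
            class = "model_comparison")
}
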