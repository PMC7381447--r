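test_that("stage-1 rank ordering puts incorrect responses first, each sorted", {
  rt <- c(300, 250, 400, 500)
  correct <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(rank_order_stage1(rt, correct), c(250, 500, 300, 400))
  # all-correct input degenerates to a plain sort
  expect_equal(rank_order_stage1(c(5, 3, 9), rep(TRUE, 3)), c(3, 5, 9))
  # permutation invariance
  set.seed(81)
  idx <- sample(4)
  expect_equal(rank_order_stage1(rt[idx], correct[idx]),
               rank_order_stage1(rt, correct))
})

test_that("stage-2 rank ordering nests correctness, trial type, then RT", {
  rt <- c(600, 350, 420, 280)
  correct <- c(FALSE, TRUE, FALSE, TRUE)
  cond <- c("BothColorMatch", "NonColorMatch",
            "NonColorMatch", "TargetColorMatch")
  # incorrect block first (Non before Both), then correct block
  expect_equal(rank_order_stage2(rt, correct, cond), c(420, 600, 350, 280))
  # within any cell the subsequence is ascending and counts are conserved
  set.seed(82)
  n <- 60
  rt2 <- sample(200:2000, n)
  c2 <- sample(c(TRUE, FALSE), n, replace = TRUE)
  k2 <- sample(condition_levels(), n, replace = TRUE)
  out <- rank_order_stage2(rt2, c2, k2)
  expect_equal(sort(out), sort(rt2))
  cells <- searchddm:::stage2_cell_counts(c2, k2)
  expect_equal(sum(cells$n), n)
  stops <- cumsum(cells$n)
  starts <- c(1, head(stops, -1) + 1)
  for (i in seq_len(nrow(cells))) {
    if (cells$n[i] > 1)
      expect_true(!is.unsorted(out[starts[i]:stops[i]]))
  }
})

test_that("the RSS is the squared gap sum and obeys Cauchy-Schwarz", {
  expect_equal(rss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rss(c(100, 200), c(110, 190)), 200)
  expect_error(rss(1:3, 1:4), class = "searchddm_data_error")
  set.seed(83)
  a <- runif(40, 200, 2000)
  b <- runif(40, 200, 2000)
  expect_gte(rss(a, b), sum(abs(a - b))^2 / 40)
})

test_that("matched simulation reproduces observed cell counts exactly", {
  params <- ddm_params(0.0015, 0.04)
  set.seed(84)
  s1 <- matched_simulation(params, NULL, c(incorrect = 7, correct = 40))
  expect_length(s1, 47)
  expect_true(!is.unsorted(s1[1:7]) && !is.unsorted(s1[8:47]))
  cells <- searchddm:::stage2_cell_counts(
    rep(c(FALSE, TRUE), c(6, 34)),
    rep(condition_levels(), length.out = 40))
  for (id in c("MIT", "SIT")) {
    set.seed(85)
    s2 <- matched_simulation(params, template_model(id, 5e-4), cells)
    expect_length(s2, 40)
  }
  # a single pure cell simulates at the base drift
  set.seed(86)
  only <- matched_simulation(params, NULL, c(incorrect = 0, correct = 5))
  expect_length(only, 5)
})

test_that("the unconditional reading lets correctness counts float", {
  params <- ddm_params(0.0011, 0.03)
  cells <- searchddm:::stage2_cell_counts(
    rep(c(FALSE, TRUE), c(6, 34)),
    rep(condition_levels(), length.out = 40))
  set.seed(95)
  u <- matched_simulation(params, template_model("MIT", 5e-4), cells,
                          matching = "unconditional")
  expect_length(u, 40)
  set.seed(96)
  u1 <- matched_simulation(params, NULL,
                           c(incorrect = 5, correct = 45),
                           matching = "unconditional")
  expect_length(u1, 50)
  # conditional matching, by contrast, reproduces the counts exactly by
  # construction (checked above); here only the totals are guaranteed
})

test_that("the SIT schedule fails to generate incorrect responses a matching template cannot produce", {
  # data from a high-accuracy regime: base errors are effectively
  # impossible (p_err << 1/1000), yet interference errors exist; under
  # SIT, a required incorrect response drawn with the non-matching (base)
  # template is then unreachable, while MIT's deterministic interference
  # drift produces it easily
  params <- ddm_params(0.003, 0.025)
  cells <- searchddm:::stage2_cell_counts(
    rep(c(FALSE, TRUE), c(8, 32)),
    rep(c("DistractorColorMatch", "NonColorMatch"),
        c(8, 32)))
  set.seed(87)
  expect_silent(matched_simulation(params, template_model("MIT", 2.5e-3),
                                   cells))
  set.seed(87)
  expect_error(matched_simulation(params, template_model("SIT", 2.5e-3),
                                  cells),
               class = "searchddm_sim_failure")
})

test_that("base parameters are recovered from a synthetic participant", {
  tt <- make_participant(88, "MIT", v = 0.0011, s = 0.03, delta = 0)
  fit <- fit_base_params(tt, seed = 880, n_rep = 2)
  expect_false(fit$fit_failed)
  expect_lt(abs(fit$drift_rate - 0.0011) / 0.0011, 0.35)
  expect_lt(abs(fit$noise_level - 0.03) / 0.03, 0.35)
  expect_gt(fit$n_eval, 49)
})

test_that("the accumulator obeys diffusion time rescaling", {
  # doubling the drift and multiplying the noise by sqrt(2) compresses
  # the first-passage time scale by two (continuum scaling; checked in a
  # fast regime where the timeout never binds)
  set.seed(89)
  a <- simulate_trials(ddm_params(0.0025, 0.02), rep(0.0025, 6000))
  b <- simulate_trials(ddm_params(0.005, 0.02 * sqrt(2)), rep(0.005, 6000))
  expect_equal(mean(b$rt) * 2 / mean(a$rt), 1, tolerance = 0.03)
  expect_equal(sd(b$rt) * 2 / sd(a$rt), 1, tolerance = 0.06)
})

test_that("the drift-rate change stage is nested in the base model", {
  tt <- make_participant(90, "MIT", delta = 8e-4)
  base <- fit_base_params(tt, seed = 900, n_rep = 2)
  fit <- fit_drift_change(tt, "MIT", base, seed = 901, n_rep = 2)
  expect_false(fit$fit_failed)
  # the optimal change parameter cannot do worse than no change at all,
  # evaluated under the same common random numbers
  real <- rank_order_stage2(tt$rt, tt$correct, tt$condition)
  cells <- searchddm:::stage2_cell_counts(tt$correct, tt$condition)
  params <- ddm_params(base$drift_rate, base$noise_level)
  at0 <- mean(sapply(1:2, function(k) {
    set.seed(901 + k - 1)
    rss(real, matched_simulation(params, template_model("MIT", 0), cells))
  }))
  expect_lte(fit$rss, at0)
  expect_gt(fit$drift_rate_change, 0)
})

test_that("identical per-model RSS vectors give t = 0 and no evidence", {
  fits <- data.frame(participant_id = letters[1:5],
                     rss_mit = c(10, 12, 14, 9, 11) * 1e5,
                     rss_sit = c(10, 12, 14, 9, 11) * 1e5,
                     mit_failed = FALSE, sit_failed = FALSE)
  cmp <- compare_models(fits)
  expect_equal(cmp$t, 0)
  expect_lt(cmp$bf10, 1)
  expect_equal(cmp$n_excluded, 0)
})

test_that("failed fits are excluded and scarce data is an analysis error", {
  fits <- data.frame(participant_id = letters[1:4],
                     rss_mit = c(1, 2, 3, 4) * 1e5,
                     rss_sit = c(2, 3, 4, 5) * 1e5,
                     mit_failed = c(FALSE, FALSE, TRUE, FALSE),
                     sit_failed = c(FALSE, TRUE, FALSE, FALSE))
  cmp <- compare_models(fits)
  expect_equal(cmp$n, 2)
  expect_equal(cmp$n_excluded, 2)
  expect_equal(cmp$favored, "MIT")
  fits$sit_failed <- TRUE
  expect_error(compare_models(fits), class = "searchddm_analysis_error")
})
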