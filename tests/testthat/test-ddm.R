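test_that("parameter validation rejects non-positive drift and noise", {
  expect_error(ddm_params(0, 0.1), class = "searchddm_param_error")
  expect_error(ddm_params(-0.01, 0.1), class = "searchddm_param_error")
  expect_error(ddm_params(0.01, 0), class = "searchddm_param_error")
  expect_error(ddm_params(0.01, 0.1, threshold = -1),
               class = "searchddm_param_error")
})

test_that("a nearly noiseless accumulator is a deterministic ramp", {
  set.seed(1)
  p <- ddm_params(0.016, 1e-12)
  sim <- simulate_trials(p, rep(0.016, 20))
  expect_true(all(sim$rt == 63L))   # ceil(threshold / drift)
  expect_true(all(sim$correct))
})

test_that("zero effective drift gives symmetric outcomes", {
  set.seed(2)
  p <- ddm_params(0.01, 0.05)
  sim <- simulate_trials(p, rep(0, 20000))
  phat <- mean(sim$correct)
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / 20000))
})

test_that("closed-form oracles match their stated values and limits", {
  expect_equal(hit_probability_oracle(0, 0.05), 0.5)
  expect_equal(hit_probability_oracle(0.005, 0.05), 0.9820, tolerance = 1e-4)
  # monotone increasing in drift
  v <- seq(-0.01, 0.01, length.out = 21)
  expect_true(all(diff(hit_probability_oracle(v, 0.05)) > 0))
  # mean decision time: strong-drift and drift-free limits
  expect_equal(mean_decision_time_oracle(10, 0.05), 1 / 10,
               tolerance = 1e-6)
  expect_equal(mean_decision_time_oracle(0, 0.05), 1 / 0.05^2)
  expect_error(hit_probability_oracle(0.01, 0),
               class = "searchddm_param_error")
})

test_that("simulation agrees with the continuum oracles in the small-step regime", {
  set.seed(3)
  p <- ddm_params(2e-4, 0.01, timeout = 100000)
  sim <- simulate_trials(p, rep(2e-4, 20000))
  p_or <- hit_probability_oracle(2e-4, 0.01)
  t_or <- mean_decision_time_oracle(2e-4, 0.01)
  expect_lt(abs(mean(sim$correct) - p_or),
            3.5 * sqrt(p_or * (1 - p_or) / 20000))
  expect_lt(abs(mean(sim$rt) - t_or), 3.5 * sd(sim$rt) / sqrt(20000))
})

test_that("coarse-step simulation carries the documented overshoot bias", {
  # at noise = 0.05 the per-sample increment overshoots the boundary by
  # ~0.58 * noise on average, inflating the effective threshold; the
  # continuum formulas remain accurate to ~1% (choice) and ~5% (time)
  set.seed(4)
  p <- ddm_params(0.005, 0.05)
  sim <- simulate_trials(p, rep(0.005, 20000))
  expect_lt(abs(mean(sim$correct) / hit_probability_oracle(0.005, 0.05) - 1),
            0.01)
  expect_lt(abs(mean(sim$rt) / mean_decision_time_oracle(0.005, 0.05) - 1),
            0.05)
  # and the bias has the predicted sign: longer times, more accuracy
  expect_gt(mean(sim$rt), mean_decision_time_oracle(0.005, 0.05))
})

test_that("choice probability rises and correct RT falls with drift", {
  drifts <- c(0.001, 0.002, 0.004, 0.008)
  stats <- sapply(drifts, function(v) {
    set.seed(5)
    sim <- simulate_trials(ddm_params(v, 0.05), rep(v, 4000))
    c(p = mean(sim$correct), rt = mean(sim$rt[sim$correct]))
  })
  expect_true(all(diff(stats["p", ]) >= 0))
  expect_true(all(diff(stats["rt", ]) < 0))
})

test_that("conditional simulation honours the required category", {
  set.seed(6)
  p <- ddm_params(0.01, 0.05)
  cor <- simulate_conditional(p, rep(0.01, 50), TRUE)
  expect_true(all(cor$rt >= 1 & cor$rt <= 2000))
  expect_true(all(cor$attempts <= 1000))
  # near-symmetric drift: incorrect responses cost about two attempts
  set.seed(7)
  inc <- simulate_conditional(ddm_params(1e-6, 0.05), rep(1e-6, 500), FALSE)
  expect_lt(abs(mean(inc$attempts) - 2), 0.25)
})

test_that("an unreachable category exhausts the attempt cap", {
  # error probability ~ exp(-2 * 0.02 / 0.01^2) is astronomically small
  set.seed(8)
  expect_error(simulate_conditional(ddm_params(0.02, 0.01), 0.02, FALSE),
               class = "searchddm_sim_failure")
})

test_that("restart-on-timeout reproduces the conditioned first-passage law", {
  # the returned RT distribution equals the unconditioned first-passage
  # distribution conditioned on finishing within the timeout
  v <- 0.0008; s <- 0.03
  set.seed(9)
  short <- simulate_trials(ddm_params(v, s, timeout = 900), rep(v, 4000))
  set.seed(10)
  long <- simulate_trials(ddm_params(v, s, timeout = 100000), rep(v, 8000))
  keep <- long$rt[long$rt <= 900]
  ks <- suppressWarnings(ks.test(short$rt + runif(4000),
                                 keep + runif(length(keep))))
  expect_gt(ks$p.value, 0.001)
  expect_true(all(short$rt <= 900))
})

test_that("a fixed seed reproduces the response sequence bit for bit", {
  p <- ddm_params(0.002, 0.04)
  set.seed(123)
  a <- simulate_trials(p, rep(0.002, 200))
  set.seed(123)
  b <- simulate_trials(p, rep(0.002, 200))
  expect_identical(a, b)
})
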