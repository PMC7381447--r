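test_that("the RT filter keeps the 200 and 2000 ms boundary values", {
  tr <- make_trials("a", rt = c(199, 200, 1000, 2000, 2001),
                    correct = TRUE)
  out <- filter_trials(tr)
  expect_equal(sort(out$trials$rt), c(200, 1000, 2000))
  expect_equal(out$report$n_in, 5L)
  expect_equal(out$report$n_kept, 3L)
})

test_that("the RT filter drops practice trials and is idempotent", {
  tr <- rbind(make_trials("a", rt = c(150, 500, 900), correct = TRUE),
              make_trials("a", rt = 500, correct = TRUE,
                          is_practice = TRUE, block = 0L))
  out <- filter_trials(tr)
  expect_equal(nrow(out$trials), 2L)
  again <- filter_trials(out$trials)
  expect_equal(again$trials$rt, out$trials$rt)
  expect_equal(again$report$n_kept, again$report$n_in)
})

test_that("empty input filters to empty output with zero counts", {
  tr <- make_trials("a", rt = 500, correct = TRUE)[0, ]
  out <- filter_trials(tr)
  expect_equal(nrow(out$trials), 0L)
  expect_equal(out$report$n_in, 0L)
})

test_that("a missing RT on a test trial is a data error", {
  tr <- make_trials("a", rt = c(500, NA), correct = TRUE)
  expect_error(filter_trials(tr), class = "searchddm_data_error")
})

test_that("the accuracy filter excludes below 0.7 and keeps 0.7 exactly", {
  tr <- rbind(make_trials("lo", rt = 500, correct = rep(c(TRUE, FALSE),
                                                        c(69, 31))),
              make_trials("at", rt = 500, correct = rep(c(TRUE, FALSE),
                                                        c(70, 30))),
              make_trials("hi", rt = 500, correct = TRUE))
  out <- exclude_participants(tr)
  expect_setequal(unique(out$trials$participant_id), c("at", "hi"))
  expect_equal(out$report$n_participants_in, 3L)
  expect_equal(out$report$n_participants_kept, 2L)
  acc <- out$report$accuracy
  expect_equal(acc$accuracy[acc$participant_id == "lo"], 0.69)
})

test_that("the full exclusion report reconciles at both levels", {
  tr <- rbind(make_trials("a", rt = c(100, rep(500, 9)), correct = TRUE),
              make_trials("b", rt = 500,
                          correct = rep(c(TRUE, FALSE), c(3, 7))))
  out <- preprocess(tr)
  expect_s3_class(out$report, "exclusion_report")
  expect_equal(out$report$n_trials_in, 20L)
  expect_equal(out$report$n_trials_kept, 9L)  # b excluded, a loses 1 trial
  expect_equal(out$report$n_participants_kept, 1L)
  expect_true(all(out$trials$participant_id == "a"))
})

test_that("a chance-level synthetic participant is excluded", {
  # drift ~ 0 yields accuracy near .5; the binomial tail at n = 256 makes
  # survival of the .7 criterion essentially impossible
  set.seed(51)
  tt <- make_participant(51, "MIT", v = 1e-6, s = 0.03, delta = 0)
  out <- exclude_participants(filter_trials(tt)$trials)
  expect_equal(out$report$n_participants_kept, 0L)
})

test_that("correct-only views group and flag cells faithfully", {
  tr <- rbind(make_trials("a", rt = 300, correct = c(TRUE, TRUE, FALSE),
                          condition = "NonColorMatch"),
              make_trials("a", rt = 400, correct = FALSE,
                          condition = "BothColorMatch"))
  view <- correct_rt_view(tr)
  non <- view[view$condition == "NonColorMatch", ]
  both <- view[view$condition == "BothColorMatch", ]
  expect_equal(non$n, 2L)
  expect_false(non$empty)
  expect_equal(both$n, 0L)   # all-incorrect cell: flagged, not fabricated
  expect_true(both$empty)
  expect_equal(length(view$rts[non$empty == FALSE][[1]]), 2L)
})

test_that("condition summaries recover generative means and effects", {
  set.seed(52)
  des <- design_spec()
  coh <- cohort_params(drift_rate_change = 8e-4, cv = 0)  # identical participants
  tr <- simulate_cohort(6, des, "MIT", coh, master_seed = 52)
  pp <- preprocess(tr)
  cs <- condition_summaries(pp$trials)
  grand <- aggregate(cbind(mean_rt, accuracy) ~ condition, cs$grand, mean)
  tgt <- grand$mean_rt[grand$condition == "TargetColorMatch"]
  non <- grand$mean_rt[grand$condition == "NonColorMatch"]
  dis <- grand$mean_rt[grand$condition == "DistractorColorMatch"]
  expect_lt(tgt, non)   # target match speeds search
  expect_gt(dis, non)   # distractor match slows it
  expect_gt(grand$accuracy[grand$condition == "TargetColorMatch"],
            grand$accuracy[grand$condition == "DistractorColorMatch"])
  # within-subject CI half-widths are positive and finite
  expect_true(all(cs$grand$rt_ci_half > 0))
  expect_true(all(is.finite(cs$grand$acc_ci_half)))
})

test_that("a single participant's grand summary equals their own summary", {
  set.seed(53)
  tt <- make_participant(53)
  cs <- condition_summaries(tt)
  merged <- merge(cs$per_participant, cs$grand,
                  by = c("condition", "congruent"))
  expect_equal(merged$mean_rt.x, merged$mean_rt.y)
  expect_true(all(is.na(cs$grand$rt_ci_half)))
})
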