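# Shared fixtures: small simulated participants/cohorts built in code.

ref_design <- function(...) design_spec(...)

# One simulated participant's test trials under a given generative model.
make_participant <- function(seed, model_id = "MIT", v = 0.0011, s = 0.03,
                             delta = 8e-4, design = design_spec(),
                             id = "p1") {
  set.seed(seed)
  tab <- build_trial_table(design, id)
  sim <- simulate_participant(tab, template_model(model_id, delta),
                              ddm_params(v, s))
  sim[!sim$is_practice, , drop = FALSE]
}

# Hand-built trial table bypassing the generator, for preprocessing tests.
make_trials <- function(participant_id, rt, correct,
                        condition = "NonColorMatch", congruent = FALSE,
                        is_practice = FALSE, block = 1L) {
  n <- max(length(participant_id), length(rt), length(correct))
  data.frame(participant_id = rep_len(participant_id, n),
             block = rep_len(block, n),
             trial = seq_len(n),
             is_practice = rep_len(is_practice, n),
             target_match = rep_len(condition %in%
               c("TargetColorMatch", "BothColorMatch"), n),
             distractor_match = rep_len(condition %in%
               c("DistractorColorMatch", "BothColorMatch"), n),
             congruent = rep_len(congruent, n),
             condition = rep_len(condition, n),
             memory_hue_1 = 0, memory_hue_2 = 90,
             rt = rep_len(rt, n),
             correct = rep_len(correct, n))
}
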