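#' Experimental design specification
#'
#' Describes the within-block factorial structure of the search task:
#' Target-Color-Match x Distractor-Color-Match x Orientation-Congruency
#' (2 x 2 x 2 = 8 cells), balanced exactly within each block. The default
#' is 8 test blocks of 32 trials (256 test trials), preceded by one flagged
#' practice block of the same size.
#'
#' @param n_blocks Number of test blocks. Default 8.
#' @param trials_per_block Trials per block; must be a multiple of 8 so the
#'   factor cells balance within block. Default 32.
#' @param include_practice Prepend one practice block (flagged
#'   `is_practice`, excluded from analysis). Default `TRUE`.
#' @param min_hue_separation Minimum circular distance in degrees between
#'   the two memory hues. Default 30.
#' @param rt_timeout Response deadline in ms. Default 2000.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_blocks = 8, trials_per_block = 32,
                        include_practice = TRUE, min_hue_separation = 30,
                        rt_timeout = 2000) {
  if (n_blocks < 1 || trials_per_block < 8)
    stop_searchddm("need n_blocks >= 1 and trials_per_block >= 8",
                   "searchddm_param_error")
  if (trials_per_block %% 8 != 0)
    stop_searchddm(
      "trials_per_block must be a multiple of 8 (the number of factor cells)",
      "searchddm_param_error")
  if (min_hue_separation <= 0 || min_hue_separation >= 180)
    stop_searchddm("min_hue_separation must lie in (0, 180)",
                   "searchddm_param_error")
  structure(list(n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 include_practice = isTRUE(include_practice),
                 min_hue_separation = min_hue_separation,
                 rt_timeout = rt_timeout),
            class = "design_spec")
}

#' Circular distance between hues
#'
#' @param a,b Hue angles in degrees.
#' @return Distance on the 360-degree circle, in `[0, 180]`.
#' @export
circular_distance <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Sample memory-color pairs on the hue circle
#'
#' Draws pairs of hues independently and uniformly on `[0, 360)` and
#' rejects pairs closer than `min_separation` degrees on the color circle,
#' so each hue is marginally uniform and the pair is uniform conditional on
#' the separation constraint.
#'
#' @param n Number of pairs.
#' @param min_separation Minimum circular distance in degrees; must lie in
#'   `(0, 180)`.
#' @return An `n x 2` matrix of hues (columns `hue_1`, `hue_2`).
#' @export
sample_memory_colors <- function(n = 1, min_separation = 30) {
  if (!is.numeric(min_separation) || length(min_separation) != 1 ||
      min_separation <= 0 || min_separation >= 180)
    stop_searchddm("min_separation must lie in (0, 180)",
                   "searchddm_param_error")
  if (n < 1) stop_searchddm("n must be >= 1", "searchddm_param_error")
  h1 <- runif(n, 0, 360)
  h2 <- runif(n, 0, 360)
  bad <- which(circular_distance(h1, h2) < min_separation)
  while (length(bad) > 0) {
    h1[bad] <- runif(length(bad), 0, 360)
    h2[bad] <- runif(length(bad), 0, 360)
    bad <- bad[circular_distance(h1[bad], h2[bad]) < min_separation]
  }
  cbind(hue_1 = h1, hue_2 = h2)
}

# One balanced, shuffled block: each of the 8 factor cells appears
# trials_per_block / 8 times.
balanced_block <- function(trials_per_block) {
  cells <- expand.grid(target_match = c(FALSE, TRUE),
                       distractor_match = c(FALSE, TRUE),
                       congruent = c(FALSE, TRUE))
  block <- cells[rep(seq_len(8), each = trials_per_block / 8), ]
  block[sample.int(nrow(block)), , drop = FALSE]
}

#' Build the trial table for one participant
#'
#' Generates the full trial sequence: one optional practice block (block 0,
#' flagged) followed by `n_blocks` test blocks, each containing every
#' factor cell exactly `trials_per_block / 8` times in random order, with a
#' fresh constrained memory-hue pair per trial. Responses (`rt`, `correct`)
#' are left missing, to be filled by a generative model
#' ([simulate_participant()]) or by real data.
#'
#' @param design A [design_spec()].
#' @param participant_id Identifier stored on every row.
#' @return A data.frame of trial records.
#' @export
build_trial_table <- function(design, participant_id = "p1") {
  stopifnot(inherits(design, "design_spec"))
  blocks <- seq_len(design$n_blocks)
  if (design$include_practice) blocks <- c(0L, blocks)
  tabs <- lapply(blocks, function(b) {
    blk <- balanced_block(design$trials_per_block)
    hues <- sample_memory_colors(nrow(blk), design$min_hue_separation)
    data.frame(participant_id = participant_id,
               block = as.integer(b),
               trial = seq_len(nrow(blk)),
               is_practice = b == 0L,
               target_match = blk$target_match,
               distractor_match = blk$distractor_match,
               congruent = blk$congruent,
               condition = condition_label(blk$target_match,
                                           blk$distractor_match),
               memory_hue_1 = hues[, "hue_1"],
               memory_hue_2 = hues[, "hue_2"],
               rt = NA_integer_,
               correct = NA,
               row.names = NULL)
  })
  do.call(rbind, tabs)
}
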