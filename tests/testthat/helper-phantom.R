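# Shared fixtures, built once per test run.

# small, fast phantom configuration used across tests
desk_phantom_config <- function(seed = 1L, n_subjects = 8L,
                                pose_jitter_px = 4, ...) {
  phantom_config(seed = seed, n_subjects = n_subjects,
                 grid_shape = c(96L, 96L, 20L),
                 in_plane_spacing_mm = c(1.4, 1.7),
                 slice_spacing_mm = c(3.0, 5.0),
                 pose_jitter_px = pose_jitter_px, ...)
}

desk_preprocess_config <- function() {
  preprocess_config(standard_inplane_px = 96L, net_input_px = 64L)
}

.fixture_env <- new.env(parent = emptyenv())

# memoised small cohort (noise and bias on)
fixture_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(desk_phantom_config())
  }
  .fixture_env$cohort
}

# memoised masked, reduced slice stacks + ages for the small cohort
fixture_stacks <- function() {
  if (is.null(.fixture_env$stacks)) {
    cfg <- pipeline_config(seed = 1, desk_scale = TRUE, n_subjects = 8L,
                           phantom = desk_phantom_config(),
                           use_truth_masks = TRUE, cv_repeats = 1)
    samples <- fixture_cohort()
    .fixture_env$stacks <- list(
      stacks = kneeage:::prepare_stacks(samples, cfg, NULL, masked = TRUE),
      ages = cohort_ages(samples))
  }
  .fixture_env$stacks
}

# brute-force zero-normalized cross-correlation oracle (R reference)
zncc_oracle <- function(image, patch) {
  pr <- nrow(patch); pc <- ncol(patch)
  p0 <- patch - mean(patch)
  pden <- sqrt(sum(p0^2))
  out <- matrix(NA_real_, nrow(image) - pr + 1, ncol(image) - pc + 1)
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      w <- image[i:(i + pr - 1), j:(j + pc - 1)]
      wss <- sum((w - mean(w))^2)
      out[i, j] <- if (wss <= 1e-12) 0 else
        sum((w - mean(w)) * p0) / (sqrt(wss) * pden)
    }
  }
  out
}

# exhaustive pair-counting AUC oracle
auc_oracle <- function(scores, minor) {
  pos <- which(minor); neg <- which(!minor)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}
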