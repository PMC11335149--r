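# Shared fixtures, all generated in code at test time.

# A small synthetic participant: short trials keep window counts and GED
# fitting fast while preserving the full 10-region structure.
tiny_rts <- function(n_trials = 8, trial_seconds = 10, seed = 42,
                     coupling = 1.0, power_ratio = 2) {
  spec <- generator_spec(
    n_participants = 1, n_trials = n_trials, trial_seconds = trial_seconds,
    planted_pairs = list(list(region_i = "RP", region_j = "LP",
                              band = "alpha", coupling = coupling,
                              coupled_class = "left")),
    lateralization = list(regions = c("LP", "RP"), band = "alpha",
                          power_ratio = power_ratio),
    seed = seed)
  generate_attention_dataset(spec)$participants[[1]]
}

# A tiny deterministic decoder for functional tests (dropout off so that
# evaluation-mode comparisons are exact).
tiny_decoder <- function(input_samples = 64, seed = 7, dropout_p = 0) {
  build_decoder(decoder_config(input_samples = input_samples,
                               dropout_p = dropout_p), seed = seed)
}

# A window set of random windows with balanced labels.
random_windows <- function(n = 8, input_samples = 64, seed = 1) {
  set.seed(seed)
  data <- array(rnorm(30 * input_samples * n), c(30, input_samples, n))
  meta <- data.frame(
    label = rep(c("left", "right"), length.out = n),
    trial_id = seq_len(n), block_id = rep(1L, n),
    participant_id = rep("S01", n), start = rep(1L, n),
    stringsAsFactors = FALSE)
  neurixn:::new_window_set(data, meta, 64, channel_index())
}

expect_same_partition <- function(a, b) {
  # two clusterings are the same partition iff their co-membership
  # indicators agree for every pair of points
  co <- function(z) outer(z, z, "==")
  expect_true(all(co(a) == co(b)))
}
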