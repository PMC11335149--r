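test_that("pair index enumerates all unordered region pairs in order", {
  pidx <- make_pair_index()
  expect_equal(pidx$n_pairs, 45)
  expect_equal(c(pidx$pairs$a[1], pidx$pairs$b[1]), c("LO", "LP"))
  expect_equal(c(pidx$pairs$a[45], pidx$pairs$b[45]), c("RC", "RF"))

  # brute-force enumeration oracle on a smaller region set
  regions4 <- c("LO", "LP", "RO", "RP")
  p4 <- make_pair_index(regions4)
  oracle <- t(utils::combn(regions4, 2))
  expect_equal(p4$n_pairs, 6)
  expect_equal(cbind(p4$pairs$a, p4$pairs$b), oracle)

  expect_error(make_pair_index(c("LO", "LO", "LP")), "distinct")
})

test_that("pair lookup is symmetric and round-trips every index", {
  pidx <- make_pair_index()
  for (k in seq_len(45)) {
    expect_identical(pair_lookup(pidx, pidx$pairs$a[k], pidx$pairs$b[k]), k)
    expect_identical(pair_lookup(pidx, pidx$pairs$b[k], pidx$pairs$a[k]), k)
  }
  expect_error(pair_lookup(pidx, "LO", "LO"), "unknown")
})

test_that("channel index is region-major, band-minor", {
  ci <- channel_index()
  expect_equal(nrow(ci), 30)
  expect_equal(ci$region[5], "LP")
  expect_equal(ci$band[5], "alpha")
  expect_equal(ci$region[1:3], rep("LO", 3))
})

test_that("sliding windows match the start-offset formula", {
  e <- enhanced_trial(matrix(rnorm(30 * 3200), 30), fs = 64, label = "left",
                      condition = "C1", trial_id = 1L)
  ws <- sliding_windows(e, 5, 0.5)
  expect_equal(length(ws), 19)
  expect_equal(dim(ws$data), c(30, 320, 19))
  expect_true(all(ws$meta$label == "left"))

  # trial length equals window length: exactly one window
  e1 <- enhanced_trial(matrix(rnorm(30 * 320), 30), 64, "right", "C1", 2L)
  expect_equal(length(sliding_windows(e1, 5, 0.5)), 1)

  # zero overlap with trial = 3 windows: non-overlapping, covering the trial
  e3 <- enhanced_trial(matrix(seq_len(30 * 960), 30), 64, "left", "C1", 3L)
  w3 <- sliding_windows(e3, 5, 0)
  expect_equal(length(w3), 3)
  expect_equal(w3$meta$start, c(1L, 321L, 641L))
  expect_equal(w3$data[, , 2], e3$data[, 321:640])

  # window longer than trial: empty with a warning
  eshort <- enhanced_trial(matrix(rnorm(30 * 100), 30), 64, "left", "C1", 4L)
  expect_warning(w0 <- sliding_windows(eshort, 5, 0.5), "longer than trial")
  expect_equal(length(w0), 0)
})

test_that("window counts match brute-force enumeration of valid starts", {
  set.seed(99)
  for (rep in 1:20) {
    n_samples <- sample(200:2000, 1)
    win_s <- sample(1:5, 1)
    ov <- sample(c(0, 0.25, 0.5, 0.75), 1)
    fs <- 64
    T_win <- round(win_s * fs)
    if (T_win > n_samples) next
    e <- enhanced_trial(matrix(0, 30, n_samples), fs, "left", "C1", 1L)
    got <- length(sliding_windows(e, win_s, ov))
    step <- max(1, round((1 - ov) * T_win))
    starts <- 0
    oracle <- 0
    s <- 1
    while (s + T_win - 1 <= n_samples) {
      oracle <- oracle + 1
      s <- s + step
    }
    expect_equal(got, oracle, info = sprintf("n=%d T=%d ov=%g", n_samples,
                                             T_win, ov))
  }
})

test_that("within-participant blocks are condition-stratified and folds rotate", {
  rts <- tiny_rts(n_trials = 60, trial_seconds = 2, seed = 5)
  splits <- make_within_splits(rts, 4, seed = 9)
  block_of <- splits[[1]]$block_of
  expect_equal(as.vector(table(block_of)), rep(15L, 4))
  # five trials of each of the three conditions per block
  tab <- table(block_of, rts$conditions)
  expect_true(all(tab == 5))
  # each block is the test block exactly once
  expect_equal(sort(vapply(splits, function(s) unique(block_of[s$test_ids]),
                           integer(1))), 1:4)
  # determinism
  splits2 <- make_within_splits(rts, 4, seed = 9)
  expect_identical(splits[[1]]$block_of, splits2[[1]]$block_of)
  # train/val/test trial ids are pairwise disjoint (no-leakage scan)
  for (s in splits) {
    expect_length(intersect(s$train_ids, s$val_ids), 0)
    expect_length(intersect(s$train_ids, s$test_ids), 0)
    expect_length(intersect(s$val_ids, s$test_ids), 0)
  }
  expect_error(make_within_splits(tiny_rts(n_trials = 3, trial_seconds = 2),
                                  4),
               "infeasible")
})

test_that("cross-participant splits produce the 90-fold leave-one-out scheme", {
  ids <- sprintf("P%02d", 1:18)
  folds <- make_cross_splits(ids, n_val = 4, n_repeats = 5, seed = 3)
  expect_length(folds, 90)
  expect_true(all(vapply(folds, function(f) length(f$train_ids), numeric(1))
                  == 13))
  # every fold partitions the participant set
  for (f in folds[c(1, 45, 90)]) {
    expect_setequal(c(f$train_ids, f$val_ids, f$test_ids), ids)
    expect_length(intersect(f$train_ids, f$val_ids), 0)
  }
  # each participant is the test set in exactly n_repeats folds
  test_ids <- vapply(folds, function(f) f$test_ids, character(1))
  expect_true(all(table(test_ids) == 5))

  # two participants, no validation: plain leave-one-out
  lou <- make_cross_splits(c("A", "B"), n_val = 0, n_repeats = 1)
  expect_length(lou, 2)
  expect_equal(lou[[1]]$train_ids, "B")
  expect_error(make_cross_splits(c("A", "B"), n_val = 1), "n_val")
})

test_that("window metadata keeps all windows of a trial in one block", {
  rts <- tiny_rts(n_trials = 8, trial_seconds = 10, seed = 2)
  splits <- make_within_splits(rts, 4, seed = 2)
  prep <- prepare_fold_windows(rts, splits[[1]], window_seconds = 2)
  m <- prep$windows$meta
  per_trial_blocks <- tapply(m$block_id, m$trial_id,
                             function(b) length(unique(b)))
  expect_true(all(per_trial_blocks == 1))
})

test_that("region trial set container round-trips through disk", {
  rts <- tiny_rts(n_trials = 4, trial_seconds = 2, seed = 8)
  dir <- withr::local_tempdir()
  write_region_trials(rts, dir)
  back <- read_region_trials(dir, rts$participant_id)
  expect_equal(back$labels, rts$labels)
  expect_equal(back$conditions, rts$conditions)
  expect_equal(back$trials, rts$trials)
  expect_equal(back$fs, rts$fs)
})
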