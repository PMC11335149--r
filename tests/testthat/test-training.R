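test_that("accuracy evaluation counts argmax agreement with labels", {
  ws <- random_windows(n = 8, seed = 21)
  model <- tiny_decoder(seed = 22)

  # matches a brute-force per-window comparison
  probs <- predict(model, ws)
  manual <- mean(c("left", "right")[max.col(probs, ties.method = "first")]
                 == ws$meta$label)
  expect_equal(evaluate_accuracy(model, ws), manual)

  # a constant-output model scores the class frequency on a balanced set
  const <- model
  const$params$W6[] <- 0
  const$params$W6[1, 1] <- 0   # logits identical -> always "left" (tie rule)
  expect_equal(evaluate_accuracy(const, ws), 0.5)

  # a perfect oracle scores 1: evaluate against its own predictions
  ws2 <- ws
  ws2$meta$label <- predict(model, ws, type = "class")
  expect_equal(evaluate_accuracy(model, ws2), 1.0)
})

test_that("training is deterministic and restores the best validation epoch", {
  rts <- tiny_rts(n_trials = 8, trial_seconds = 10, seed = 31)
  splits <- make_within_splits(rts, 4, seed = 31)
  prep <- prepare_fold_windows(rts, splits[[1]], window_seconds = 1)
  cfg <- decoder_config(input_samples = 64)
  r1 <- train_decoder(build_decoder(cfg, seed = 5), splits[[1]],
                      prep$windows, epochs = 3, seed = 5)
  r2 <- train_decoder(build_decoder(cfg, seed = 5), splits[[1]],
                      prep$windows, epochs = 3, seed = 5)
  expect_identical(r1$val_loss_curve, r2$val_loss_curve)
  expect_identical(r1$model$params, r2$model$params)

  # validation stopping: the selected epoch attains the curve minimum
  expect_equal(r1$best_epoch, which.min(r1$val_loss_curve))
  expect_equal(min(r1$val_loss_curve), r1$val_loss_curve[r1$best_epoch])

  # max-norm constraint holds after training
  norms <- sqrt(rowSums(r1$model$params$w4^2))
  expect_true(all(norms <= 1 + 1e-6))

  expect_error(train_decoder(build_decoder(cfg, seed = 1),
                             neurixn:::new_cv_split(1, 1:2, 3, integer(0),
                                                    "within"),
                             prep$windows, epochs = 1),
               "infeasible")
})

test_that("cross-participant folds train on pooled other-participant windows", {
  spec <- generator_spec(n_participants = 3, n_trials = 4, trial_seconds = 6,
                         seed = 35)
  ds <- generate_attention_dataset(spec)
  all_w <- bind_windows(lapply(ds$participants, function(rts) {
    comps <- fit_gedb_components(rts)
    enh <- enhance_participant(rts, comps)
    bind_windows(lapply(enh, sliding_windows, window_seconds = 1,
                        overlap_fraction = 0.5,
                        participant_id = rts$participant_id))
  }))
  folds <- make_cross_splits(sprintf("S%02d", 1:3), n_val = 1,
                             n_repeats = 1, seed = 35)
  model <- build_decoder(decoder_config(input_samples = 64), seed = 35)
  rep <- train_decoder(model, folds[[1]], all_w, epochs = 2, seed = 35)
  expect_length(rep$val_loss_curve, 2)
  expect_gte(rep$test_accuracy, 0)
  expect_lte(rep$test_accuracy, 1)
  # the fold's test windows come from exactly the held-out participant
  test_w <- neurixn:::split_window_sets(folds[[1]], all_w)$test
  expect_setequal(unique(test_w$meta$participant_id), folds[[1]]$test_ids)
})

test_that("band-power features summarize spectral content region by region", {
  feats_len <- 10 * 4
  set.seed(41)
  x <- matrix(rnorm(30 * 640, sd = 0.1), 30)
  # put a strong 10 Hz tone into region LP (rows 4:6)
  tone <- 3 * sin(2 * pi * 10 * seq_len(640) / 64)
  x[4:6, ] <- x[4:6, ] + rep(tone, each = 3)
  f <- bandpower_features(x, fs = 64)
  expect_length(f, feats_len)
  lp <- f[grepl("^LP_", names(f))]
  expect_equal(names(which.max(lp)), "LP_alpha")

  # zero input collapses to the log floor
  f0 <- bandpower_features(matrix(0, 30, 640), fs = 64)
  expect_true(all(f0 == log10(1e-12)))

  expect_error(bandpower_features(matrix(0, 30, 32), fs = 64), "too short")
})

test_that("the logistic baseline learns separable band-power structure", {
  ws <- random_windows(n = 40, input_samples = 128, seed = 51)
  # amplify alpha-band content of RP for class left: inject a 10 Hz tone
  tone <- 2 * sin(2 * pi * 10 * seq_len(128) / 64)
  for (k in which(ws$meta$label == "left")) {
    ws$data[19:21, , k] <- ws$data[19:21, , k] + rep(tone, each = 3)
  }
  ws$meta$trial_id <- seq_len(40)
  split <- neurixn:::new_cv_split(1, train_ids = 1:20, val_ids = 21:30,
                                  test_ids = 31:40, scope = "within")
  fit <- train_baseline(ws, split, seed = 1, iters = 1000)
  expect_length(fit$model$weights, 40)
  expect_gte(fit$report$test_accuracy, 0.7)

  # all-identical features: accuracy falls back to the class prior
  const_feats <- matrix(1, 40, 40,
                        dimnames = list(NULL, names(fit$model$weights)))
  fit0 <- train_baseline(ws, split, seed = 1, iters = 50,
                         features = const_feats)
  expect_gte(fit0$report$test_accuracy, 0.3)
  expect_lte(fit0$report$test_accuracy, 0.7)

  # region/band weight knockout mirrors the decoder ablation machinery
  ab <- ablate_baseline(fit$model, regions = "RP")
  expect_equal(sum(ab$weights[grepl("^RP_", names(ab$weights))] != 0), 0)
  expect_equal(sum(ab$weights == 0) - sum(fit$model$weights == 0), 4)
  ab2 <- ablate_baseline(fit$model, bands = "alpha")
  expect_equal(sum(ab2$weights == 0) - sum(fit$model$weights == 0), 10)
  ab3 <- ablate_baseline(fit$model, lobes = "parietal")
  expect_equal(sum(ab3$weights == 0) - sum(fit$model$weights == 0), 8)
})

test_that("fold accuracies aggregate to per-participant means and a median", {
  reports <- list(
    list(participant_id = "S1", test_accuracy = 0.6),
    list(participant_id = "S1", test_accuracy = 0.8),
    list(participant_id = "S2", test_accuracy = 0.7),
    list(participant_id = "S3", test_accuracy = 0.8))
  agg <- aggregate_results(reports)
  expect_equal(agg$per_participant$mean_accuracy, c(0.7, 0.7, 0.8))
  expect_equal(agg$median_accuracy, 0.7)
  # invariant to report order
  agg2 <- aggregate_results(rev(reports))
  expect_equal(agg2$per_participant, agg$per_participant)
  # single report: the median is that accuracy
  expect_equal(aggregate_results(reports[3])$median_accuracy, 0.7)
})
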