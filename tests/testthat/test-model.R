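test_that("stage shapes follow the 30 -> 45 -> pooled contract", {
  model <- build_decoder(decoder_config(input_samples = 320), seed = 1)
  X <- array(rnorm(30 * 320 * 2), c(30, 320, 2))
  out <- neurixn:::decoder_forward(model, X, return_stages = TRUE)
  expect_length(out$stages$temporal_maps, 4)
  expect_equal(dim(out$stages$temporal_maps[[1]]), c(30, 320, 2))
  expect_equal(dim(out$stages$region_signals[[1]]), c(10, 320, 2))
  expect_equal(dim(out$stages$interactions[[1]]), c(45, 320, 2))
  # pooling after the interaction layer: 320 samples over 5 s -> 80 = 16 Hz
  expect_equal(dim(out$stages$pooled), c(4, 80, 2))
  expect_equal((dim(out$stages$pooled)[2] / 5), 16)
  expect_equal(dim(out$stages$features), c(40, 2))
})

test_that("the interaction stage is the exact pairwise product", {
  pidx <- make_pair_index()
  ones <- matrix(1, 10, 7)
  expect_equal(interaction_stage(ones, pidx), matrix(1, 45, 7))

  consts <- matrix(rep(1:10, 4), 10)
  got <- interaction_stage(consts, pidx)
  oracle <- t(apply(utils::combn(10, 2), 2, prod))
  expect_equal(got[, 1], as.vector(oracle))
  expect_equal(nrow(got), 45)

  # symmetric in the two members of a pair
  set.seed(1)
  x <- matrix(rnorm(10 * 16), 10)
  for (k in c(1, 17, 45)) {
    i <- pidx$pairs$i[k]
    j <- pidx$pairs$j[k]
    expect_equal(interaction_stage(x, pidx)[k, ], x[j, ] * x[i, ])
  }
  expect_error(interaction_stage(matrix(0, 9, 5), pidx))
})

test_that("forward output is a probability distribution per window", {
  model <- tiny_decoder()
  X <- array(rnorm(30 * 64 * 5), c(30, 64, 5))
  p <- predict(model, X)
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_true(all(p >= 0))

  # per-sample independence: duplicating a window duplicates its row
  X2 <- X
  X2[, , 5] <- X[, , 1]
  p2 <- predict(model, X2)
  expect_equal(p2[5, ], p2[1, ])

  # identical inputs in one batch give identical outputs (eval mode)
  Z <- array(0, c(30, 64, 2))
  pz <- predict(model, Z)
  expect_equal(pz[1, ], pz[2, ])

  expect_error(predict(model, array(0, c(29, 64, 1))), "channels")
  expect_error(predict(model, array(0, c(30, 32, 1))), "samples")
})

test_that("spatial filters extract, replace and count as documented", {
  model <- build_decoder(decoder_config(input_samples = 320), seed = 2)
  sf <- extract_spatial_filters(model)
  expect_equal(dim(sf$filters), c(4, 45))

  new_f <- matrix(seq_len(180) / 180, 4, 45)
  model2 <- set_spatial_filters(model, new_f)
  expect_identical(extract_spatial_filters(model2)$filters, new_f)
  # original untouched
  expect_identical(extract_spatial_filters(model)$filters, sf$filters)

  # parameter count: closed form and tensor enumeration agree
  closed_form <- 4 * 31 + 2 * 4 +          # temporal kernels + BN
    4 * 10 * 3 + 4 * 10 * 31 +             # grouped pointwise + depthwise
    4 * 45 + 2 * 4 +                       # spatial filters + BN
    4 * 16 + 4 * 4 + 2 * 4 +               # separable + BN
    2 * 40                                 # classifier
  expect_equal(count_parameters(model), closed_form)
  expect_equal(count_parameters(model), 1848)
  enumerated <- sum(vapply(model$params, length, numeric(1)))
  expect_equal(count_parameters(model), enumerated)

  # doubling the temporal maps doubles the stage-1 kernel count
  m8 <- build_decoder(decoder_config(input_samples = 320,
                                     n_temporal_maps = 8), seed = 2)
  expect_equal(length(m8$params$k1), 2 * length(model$params$k1))
})

test_that("analytic gradients match finite differences for every tensor", {
  model <- tiny_decoder(seed = 11)
  set.seed(12)
  X <- array(rnorm(30 * 64 * 3), c(30, 64, 3))
  y <- neurixn:::label_onehot(c("left", "right", "left"))
  out <- neurixn:::decoder_forward(model, X, training = TRUE,
                                   want_cache = TRUE)
  grads <- neurixn:::decoder_backward(out$model, out$cache,
                                      (out$probs - y) / 3)
  loss_at <- function(m) {
    neurixn:::cross_entropy(
      neurixn:::decoder_forward(m, X, training = TRUE)$probs, y)
  }
  eps <- 1e-5
  set.seed(13)
  for (nm in names(model$params)) {
    for (i in sample(length(model$params[[nm]]),
                     min(4, length(model$params[[nm]])))) {
      mp <- model; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm <- model; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                   info = paste("tensor", nm, "entry", i))
    }
  }
})

test_that("region knockout makes logits exactly invariant to that region", {
  model <- tiny_decoder(seed = 3)
  pidx <- model$pair_index
  set.seed(4)
  X <- array(rnorm(30 * 64 * 2), c(30, 64, 2))

  ablated <- apply_kernel_mask(model, region_mask("parietal", pidx))
  base <- neurixn:::decoder_forward(ablated, X)$logits
  # perturb only the parietal input channels (LP rows 4:6, RP rows 19:21)
  rows <- which(channel_index()$region %in% c("LP", "RP"))
  Xp <- X
  Xp[rows, , ] <- Xp[rows, , ] + 10 * rnorm(length(rows) * 64 * 2)
  expect_identical(neurixn:::decoder_forward(ablated, Xp)$logits, base)

  # full 45-index mask: logits invariant to any input perturbation
  full <- neurixn:::new_ablation_mask("cluster", seq_len(45))
  dead <- apply_kernel_mask(model, full)
  l1 <- neurixn:::decoder_forward(dead, X)$logits
  l2 <- neurixn:::decoder_forward(dead, X + rnorm(length(X)))$logits
  expect_identical(l1, l2)
})
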