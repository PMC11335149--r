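test_that("zero-phase band-pass preserves in-band and rejects out-of-band tones", {
  fs <- 64
  t <- seq(0, 10, by = 1 / fs)[-1]
  trim <- 65:(length(t) - 64)   # drop one second of edge at each end

  in_band <- sin(2 * pi * 10 * t)
  y <- bandpass_filter(in_band, 8, 13, fs)
  amp_ratio <- stats::sd(y[trim]) / stats::sd(in_band[trim])
  expect_gt(amp_ratio, 0.95)
  expect_lt(amp_ratio, 1.05)

  out_band <- sin(2 * pi * 20 * t)
  y2 <- bandpass_filter(out_band, 8, 13, fs)
  atten_db <- 20 * log10(stats::sd(y2[trim]) / stats::sd(out_band[trim]))
  expect_lt(atten_db, -20)

  expect_equal(bandpass_filter(rep(0, 256), 8, 13, fs), rep(0, 256))
  expect_error(bandpass_filter(rnorm(256), 20, 40, fs), "invalid band")
})

test_that("identical signal and reference covariances give unit eigenvalue", {
  set.seed(1)
  S <- crossprod(matrix(rnorm(16), 4))
  cmp <- gedb_first_component(band = band_spec("alpha", 8, 13), fs = 64,
                              shrinkage = 0, cov_signal = S,
                              cov_reference = S)
  expect_equal(cmp$eigenvalue, 1, tolerance = 1e-8)
})

test_that("the first component recovers a planted narrowband source", {
  set.seed(2)
  fs <- 64
  n <- 4096
  tone <- sin(2 * pi * 10 * seq_len(n) / fs)
  src <- rbind(tone + 0.1 * rnorm(n), rnorm(n))
  cmp <- gedb_first_component(src, band_spec("alpha", 8, 13), fs)
  comp_tc <- as.vector(crossprod(cmp$weights, src))
  expect_gt(abs(stats::cor(comp_tc, tone)), 0.95)
})

test_that("generalized eigensolve matches the whitening oracle", {
  whitening_oracle <- function(S, R) {
    e <- eigen(R, symmetric = TRUE)
    Rs <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
    M <- Rs %*% S %*% Rs
    ee <- eigen((M + t(M)) / 2, symmetric = TRUE)
    w <- Rs %*% ee$vectors[, 1]
    w <- w / sqrt(sum(w^2))
    list(w = w * sign(w[which.max(abs(w))]), lambda = ee$values[1])
  }
  set.seed(3)
  for (i in 1:20) {
    X <- matrix(rnorm(4 * 2000), 4)
    Xf <- bandpass_filter(X, 8, 13, 64)
    S <- neurixn:::row_cov(Xf)
    R <- neurixn:::regularize_cov(neurixn:::row_cov(X), 0.01)
    cmp <- gedb_first_component(band = band_spec("alpha", 8, 13), fs = 64,
                                shrinkage = 0, cov_signal = S,
                                cov_reference = R)
    orc <- whitening_oracle(S, R)
    expect_lt(max(abs(cmp$weights - orc$w)), 1e-6)
    expect_equal(cmp$eigenvalue, orc$lambda, tolerance = 1e-8)
  }
})

test_that("GED eigenvalues are invariant to invertible source mixing", {
  set.seed(4)
  X <- matrix(rnorm(4 * 3000), 4)
  X[1, ] <- X[1, ] + 2 * bandpass_filter(rnorm(3000), 8, 13, 64)
  ev <- function(sources) {
    gedb_first_component(sources, band_spec("alpha", 8, 13), 64,
                         shrinkage = 0)$eigenvalue
  }
  lam <- ev(X)
  for (i in 1:5) {
    A <- matrix(rnorm(16), 4)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(16), 4)
    expect_equal(ev(A %*% X), lam, tolerance = 1e-6)
  }
})

test_that("the first component maximizes the band-power Rayleigh quotient", {
  set.seed(5)
  X <- matrix(rnorm(4 * 3000), 4)
  X[2, ] <- X[2, ] + bandpass_filter(rnorm(3000), 8, 13, 64)
  Xf <- bandpass_filter(X, 8, 13, 64)
  S <- neurixn:::row_cov(Xf)
  R <- neurixn:::row_cov(X)
  ratio <- function(w) as.numeric(crossprod(w, S %*% w) /
                                    crossprod(w, R %*% w))
  cmp <- gedb_first_component(band = band_spec("alpha", 8, 13), fs = 64,
                              shrinkage = 0, cov_signal = S,
                              cov_reference = R)
  best <- ratio(cmp$weights)
  # beats every individual source
  for (j in 1:4) expect_gte(best + 1e-10, ratio(diag(4)[, j]))
  # beats random unit vectors
  for (i in 1:200) {
    w <- rnorm(4)
    expect_gte(best + 1e-10, ratio(w / sqrt(sum(w^2))))
  }
})

test_that("trial enhancement yields 30 standardized channels in canonical order", {
  rts <- tiny_rts(n_trials = 4, trial_seconds = 4, seed = 6)
  comps <- fit_gedb_components(rts, trial_ids = 1:2)
  enh <- enhance_trial(rts$trials[[1]], fs = rts$fs, components = comps,
                       label = rts$labels[1], condition = rts$conditions[1],
                       trial_id = 1L)
  expect_equal(nrow(enh$data), 30)
  expect_equal(enh$channel_index$region[5], "LP")
  expect_equal(enh$channel_index$band[5], "alpha")
  expect_lt(max(abs(rowMeans(enh$data))), 1e-10)
  expect_equal(apply(enh$data, 1, stats::sd), rep(1, 30), tolerance = 1e-8)

  expect_error(enhance_trial(rts$trials[[1]][1:9], fs = rts$fs),
               "invalid region")
})

test_that("one source per region degenerates to the standardized input", {
  set.seed(7)
  n <- 512
  srcs <- lapply(canonical_region_order(), function(r) {
    matrix(rnorm(n), 1)
  })
  names(srcs) <- canonical_region_order()
  enh <- enhance_trial(srcs, fs = 64)
  for (r in seq_len(10)) {
    x <- as.vector(srcs[[r]])
    for (b in 1:3) {
      ch <- enh$data[(r - 1) * 3 + b, ]
      expect_equal(abs(stats::cor(ch, x)), 1, tolerance = 1e-10)
    }
  }
})
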