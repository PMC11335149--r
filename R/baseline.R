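# Band-power logistic-regression baseline.  Each input is summarized as 40
# log band-power features (10 regions x delta/theta/alpha/beta), fed to a
# single sigmoid unit trained by full-batch gradient descent on binary
# cross-entropy with the same best-validation-epoch selection as the
# decoder.

welch_psd <- function(x, fs, nperseg = min(length(x), 2 * fs),
                      overlap = 0.5) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- 0.54 - 0.46 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  scale <- fs * sum(win^2)
  nf <- nperseg %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    px <- Mod(stats::fft(seg))^2 / scale
    acc <- acc + px[seq_len(nf)]
  }
  psd <- acc / length(starts)
  psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]  # one-sided
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = psd)
}

#' Band-power feature vector of one input
#'
#' Per region, the mean Welch power of that region's combined signal (the
#' mean of its three enhanced channels) in each of the four canonical bands
#' (delta 2-4, theta 4-8, alpha 8-13, beta 15-32 Hz), log10-scaled with a
#' small floor so that zero signal maps to a finite constant.  Region-major,
#' band-minor ordering gives the 40-dimensional baseline input.
#'
#' @param x An [enhanced_trial()] or a 30 x T numeric matrix.
#' @param fs Sampling rate (taken from `x` when it is an enhanced trial).
#' @param bands Named list of four [band_spec()]s; default [baseline_bands()].
#' @param power_floor Additive floor before the log (default 1e-12).
#' @return Named numeric vector of length `10 * length(bands)`.
#' @export
bandpower_features <- function(x, fs = 64, bands = baseline_bands(),
                               power_floor = 1e-12) {
  if (inherits(x, "enhanced_trial")) {
    fs <- x$fs
    x <- x$data
  }
  stopifnot(is.matrix(x), nrow(x) %% 3 == 0)
  lowest <- min(vapply(bands, `[[`, numeric(1), "low_hz"))
  if (ncol(x) < 2 * fs / lowest) {
    stop("input too short: need at least two periods of the lowest band",
         call. = FALSE)
  }
  regions <- canonical_region_order()
  feats <- numeric(0)
  for (r in seq_along(regions)) {
    combined <- colMeans(x[(r - 1) * 3 + 1:3, , drop = FALSE])
    w <- welch_psd(combined, fs)
    for (bn in names(bands)) {
      b <- bands[[bn]]
      sel <- w$freq >= b$low_hz & w$freq < b$high_hz
      feats <- c(feats, log10(mean(w$psd[sel]) + power_floor))
    }
  }
  names(feats) <- paste(rep(regions, each = length(bands)),
                        rep(names(bands), length(regions)), sep = "_")
  feats
}

#' Band-power features for every window in a window set
#'
#' @param windows A `window_set`.
#' @param bands Band list as in [bandpower_features()].
#' @return Numeric matrix (n_windows x 40) with named columns.
#' @export
bandpower_matrix <- function(windows, bands = baseline_bands()) {
  n <- length(windows)
  out <- t(vapply(seq_len(n), function(k) {
    bandpower_features(windows$data[, , k], windows$fs, bands)
  }, numeric(10 * length(bands))))
  out
}

#' Train the band-power logistic baseline on one fold
#'
#' Full-batch gradient descent on binary cross-entropy (positive class
#' "right"), features z-scored with training-set statistics, keeping the
#' iteration with the lowest validation loss.
#'
#' @param windows A `window_set`.
#' @param split A `cv_split` (same semantics as [train_decoder()]).
#' @param seed Integer seed (kept for protocol symmetry; the fit itself is
#'   deterministic).
#' @param lr Gradient-descent learning rate.
#' @param iters Number of iterations.
#' @param features Optional precomputed feature matrix aligned to `windows`.
#' @return List with `model` (a `baseline_model`: `weights` (40),
#'   `intercept`, z-scoring constants) and `report` (best iteration,
#'   validation curve, test accuracy).
#' @export
train_baseline <- function(windows, split, seed = 1, lr = 0.05, iters = 2000,
                           features = NULL) {
  if (is.null(features)) features <- bandpower_matrix(windows)
  sets_idx <- baseline_split_idx(split, windows)
  if (!length(sets_idx$train) || !length(sets_idx$val) ||
      !length(sets_idx$test)) {
    stop("infeasible split: empty train/val/test set", call. = FALSE)
  }
  y <- as.numeric(windows$meta$label == "right")
  mu <- colMeans(features[sets_idx$train, , drop = FALSE])
  sdv <- apply(features[sets_idx$train, , drop = FALSE], 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(features, 2, mu), 2, sdv, "/")
  Xtr <- Xs[sets_idx$train, , drop = FALSE]; ytr <- y[sets_idx$train]
  Xva <- Xs[sets_idx$val, , drop = FALSE]; yva <- y[sets_idx$val]

  set.seed(seed)
  w <- numeric(ncol(Xs)); b <- 0
  best <- list(loss = Inf, w = w, b = b, iter = 0L)
  val_curve <- numeric(iters)
  for (it in seq_len(iters)) {
    p <- stats::plogis(as.vector(Xtr %*% w) + b)
    err <- p - ytr
    w <- w - lr * as.vector(crossprod(Xtr, err)) / length(ytr)
    b <- b - lr * mean(err)
    pv <- stats::plogis(as.vector(Xva %*% w) + b)
    val_curve[it] <- bce_loss(pv, yva)
    if (val_curve[it] < best$loss) {
      best <- list(loss = val_curve[it], w = w, b = b, iter = it)
    }
  }
  model <- structure(list(weights = stats::setNames(best$w, colnames(features)),
                          intercept = best$b, feature_mean = mu,
                          feature_sd = sdv),
                     class = "baseline_model")
  acc <- baseline_accuracy(model, features[sets_idx$test, , drop = FALSE],
                           windows$meta$label[sets_idx$test])
  list(model = model,
       report = list(best_iter = best$iter, val_loss_curve = val_curve,
                     test_accuracy = acc, fold_id = split$fold_id))
}

baseline_split_idx <- function(split, windows) {
  m <- windows$meta
  if (split$scope == "within") {
    list(train = which(m$trial_id %in% split$train_ids),
         val = which(m$trial_id %in% split$val_ids),
         test = which(m$trial_id %in% split$test_ids))
  } else {
    list(train = which(m$participant_id %in% split$train_ids),
         val = which(m$participant_id %in% split$val_ids),
         test = which(m$participant_id %in% split$test_ids))
  }
}

bce_loss <- function(p, y, eps = 1e-12) {
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

#' Predicted probability of attending right, for the baseline
#'
#' @param model A `baseline_model`.
#' @param features Feature matrix (n x 40), unscaled.
#' @return Numeric vector of probabilities.
#' @export
predict_baseline <- function(model, features) {
  Xs <- sweep(sweep(features, 2, model$feature_mean), 2, model$feature_sd, "/")
  stats::plogis(as.vector(Xs %*% model$weights) + model$intercept)
}

baseline_accuracy <- function(model, features, labels) {
  pred <- ifelse(predict_baseline(model, features) > 0.5, "right", "left")
  mean(pred == labels)
}

#' Ablate baseline weights by region or band
#'
#' Mirrors the decoder's kernel knockout: zeroes the weights of all features
#' belonging to the given single regions (4 entries each), lobes (both
#' hemispheres, 8 entries each) and/or bands (10 entries each).
#'
#' @param model A `baseline_model`.
#' @param regions Character vector of region codes (e.g. "RP"), or `NULL`.
#' @param lobes Character vector of lobe names
#'   (occipital/parietal/temporal/central/frontal), or `NULL`.
#' @param bands Character vector of band names (delta/theta/alpha/beta), or
#'   `NULL`.
#' @return A modified copy of the model.
#' @export
ablate_baseline <- function(model, regions = NULL, lobes = NULL,
                            bands = NULL) {
  nm <- names(model$weights)
  region <- sub("_.*$", "", nm)
  band <- sub("^[A-Z]+_", "", nm)
  zero <- rep(FALSE, length(nm))
  if (!is.null(regions)) zero <- zero | region %in% regions
  if (!is.null(lobes)) zero <- zero | region_lobe(region) %in% lobes
  if (!is.null(bands)) zero <- zero | band %in% bands
  model$weights[zero] <- 0
  model
}
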