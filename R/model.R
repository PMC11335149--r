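# The interaction decoder.  Stages, for a 30 x T window (10 regions x 3
# enhancement bands):
#
#   1. temporal convolution: 4 kernels of shape (1, 31), same padding, no
#      bias, batch normalization per temporal map            -> 4 x 30 x T
#   2. per-map grouped pointwise convolution collapsing each region's 3 band
#      channels to 1, then depthwise temporal convolution (10 groups, kernel
#      31)                                                   -> 4 x 10 x T
#   3. interaction stage: element-wise products of all 45 unordered region
#      pairs per map                                         -> 4 x 45 x T
#   4. depthwise spatial convolution, one (45, 1) kernel per map with a
#      max-norm-1 constraint, batch norm, ELU, average pooling (1, 4),
#      dropout 0.5                                           -> 4 x T/4
#   5. separable convolution (depthwise temporal kernel 16, then pointwise
#      4 -> 4), batch norm, ELU, average pooling (1, 8), dropout -> 4 x T/32
#   6. flatten, bias-free linear map to 2 units, softmax.
#
# All convolutions are bias-free.  The (45, 1) kernels of stage 4 are the
# "spatial filters": the only route from the input to the classifier passes
# through the 45 pairwise-product channels, so these four 45-vectors state
# directly which region interactions the decoder uses.

#' Decoder configuration
#'
#' @param input_samples Window length in samples (e.g. 320 for 5 s at 64 Hz).
#' @param fs Sampling rate of the input windows, Hz.
#' @param n_regions,n_bands Input layout; `n_regions * n_bands` channels.
#' @param n_temporal_maps Number of temporal feature maps (F1); the number of
#'   spatial filters equals it (depthwise pairing).
#' @param temporal_kernel_len Length of the stage-1/2 temporal kernels
#'   (odd; 31 at 64 Hz, about half the sampling rate).
#' @param pool1,pool2 Average-pooling widths after the interaction stage and
#'   after the separable stage.
#' @param separable_kernel_len Depthwise kernel length of the separable
#'   stage (16 samples = 1 s at the post-pool rate of 16 Hz).
#' @param dropout_p Dropout probability.
#' @param maxnorm Maximum Euclidean norm of each spatial-filter row.
#' @param n_classes Number of output classes.
#' @param bn_momentum,bn_eps Batch-normalization running-statistics momentum
#'   and variance floor.
#' @return A `decoder_config` list.
#' @export
decoder_config <- function(input_samples = 320, fs = 64, n_regions = 10,
                           n_bands = 3, n_temporal_maps = 4,
                           temporal_kernel_len = 31, pool1 = 4, pool2 = 8,
                           separable_kernel_len = 16, dropout_p = 0.5,
                           maxnorm = 1.0, n_classes = 2, bn_momentum = 0.1,
                           bn_eps = 1e-5) {
  if (temporal_kernel_len %% 2 == 0) {
    stop("temporal_kernel_len must be odd", call. = FALSE)
  }
  if ((input_samples %/% pool1) < 1 ||
      ((input_samples %/% pool1) %/% pool2) < 1) {
    stop("input too short for the pooling cascade", call. = FALSE)
  }
  structure(list(input_samples = input_samples, fs = fs,
                 n_regions = n_regions, n_bands = n_bands,
                 n_temporal_maps = n_temporal_maps,
                 n_spatial_filters = n_temporal_maps,
                 temporal_kernel_len = temporal_kernel_len,
                 pool1 = pool1, pool2 = pool2,
                 separable_kernel_len = separable_kernel_len,
                 dropout_p = dropout_p, maxnorm = maxnorm,
                 n_classes = n_classes, bn_momentum = bn_momentum,
                 bn_eps = bn_eps),
            class = "decoder_config")
}

#' Build an interaction decoder
#'
#' Initializes all trainable tensors (uniform in
#' `+/- 1/sqrt(fan_in)` per tensor, seeded) and the batch-normalization
#' running statistics.
#'
#' @param config A [decoder_config()].
#' @param pair_index Pair index; defaults to the canonical 45 pairs.
#' @param seed Integer seed for the initialization.
#' @return An object of class `neurixn_decoder`.
#' @export
build_decoder <- function(config = decoder_config(),
                          pair_index = make_pair_index(), seed = 1) {
  cfg <- config
  M <- cfg$n_temporal_maps
  R <- cfg$n_regions
  L <- cfg$temporal_kernel_len
  Ls <- cfg$separable_kernel_len
  n_pairs <- pair_index$n_pairs
  T4 <- cfg$input_samples %/% cfg$pool1
  T5 <- T4 %/% cfg$pool2
  set.seed(seed)
  u <- function(n, fan_in) {
    a <- sqrt(1 / fan_in)
    stats::runif(n, -a, a)
  }
  params <- list(
    k1 = matrix(u(M * L, L), M, L),
    w2 = array(u(M * R * cfg$n_bands, cfg$n_bands), c(M, R, cfg$n_bands)),
    k2 = array(u(M * R * L, L), c(M, R, L)),
    w4 = matrix(u(M * n_pairs, n_pairs), M, n_pairs),
    k5 = matrix(u(M * Ls, Ls), M, Ls),
    p5 = matrix(u(M * M, M), M, M),
    W6 = matrix(u(cfg$n_classes * M * T5, M * T5), cfg$n_classes, M * T5),
    bn1_g = rep(1, M), bn1_b = rep(0, M),
    bn4_g = rep(1, M), bn4_b = rep(0, M),
    bn5_g = rep(1, M), bn5_b = rep(0, M))
  params$w4 <- maxnorm_project_rows(params$w4, cfg$maxnorm)
  state <- list(bn1_rm = rep(0, M), bn1_rv = rep(1, M),
                bn4_rm = rep(0, M), bn4_rv = rep(1, M),
                bn5_rm = rep(0, M), bn5_rv = rep(1, M))
  structure(list(config = cfg, pair_index = pair_index, params = params,
                 state = state, meta = list(seed = seed)),
            class = "neurixn_decoder")
}

#' @export
print.neurixn_decoder <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<neurixn_decoder> %d x %d input, %d temporal maps, %d interaction channels, %d parameters\n",
    cfg$n_regions * cfg$n_bands, cfg$input_samples, cfg$n_temporal_maps,
    x$pair_index$n_pairs, count_parameters(x)))
  invisible(x)
}

#' Pairwise interaction stage
#'
#' Row `k` of the output is the element-wise product of the two region rows
#' named by pair `k` of the pair index.  Symmetric in the two regions of each
#' pair.
#'
#' @param region_signals Numeric matrix (n_regions x T).
#' @param pair_index A [make_pair_index()] object over the same regions.
#' @return Numeric matrix (n_pairs x T).
#' @export
interaction_stage <- function(region_signals, pair_index = make_pair_index()) {
  stopifnot(is.matrix(region_signals),
            nrow(region_signals) == length(pair_index$region_order))
  p <- pair_index$pairs
  region_signals[p$i, , drop = FALSE] * region_signals[p$j, , drop = FALSE]
}

#' Total number of trainable parameters
#'
#' Counts every trainable scalar by enumerating the parameter tensors.  With
#' the default configuration the closed form is
#' `4*31 + 2*4` (temporal kernels + BN) `+ 4*10*3` (grouped pointwise)
#' `+ 4*10*31` (depthwise temporal) `+ 4*45 + 2*4` (spatial filters + BN)
#' `+ 4*16 + 4*4 + 2*4` (separable + BN) `+ 2*40` (classifier) `= 1848`.
#'
#' @param model A `neurixn_decoder`.
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' Extract the spatial filters of a decoder
#'
#' Returns the four (45, 1) depthwise spatial-convolution kernels applied to
#' the interaction channels, rows aligned to temporal maps and columns to
#' the pair index.
#'
#' @param model A `neurixn_decoder`.
#' @param fold_id,participant_id Optional provenance tags.
#' @return A `spatial_filter_set`: list with `filters`
#'   (n_maps x n_pairs matrix), `pair_index`, `fold_id`, `participant_id`.
#' @export
extract_spatial_filters <- function(model, fold_id = NA,
                                    participant_id = NA) {
  structure(list(filters = model$params$w4, pair_index = model$pair_index,
                 fold_id = fold_id, participant_id = participant_id),
            class = "spatial_filter_set")
}

#' Replace the spatial filters of a decoder
#'
#' @param model A `neurixn_decoder`.
#' @param filters Numeric matrix (n_maps x n_pairs).
#' @return The modified decoder (a copy).
#' @export
set_spatial_filters <- function(model, filters) {
  stopifnot(identical(dim(filters), dim(model$params$w4)))
  model$params$w4 <- filters
  model
}

# --- forward / backward ----------------------------------------------------

decoder_forward <- function(model, X, training = FALSE, want_cache = FALSE,
                            return_stages = FALSE) {
  cfg <- model$config
  p <- model$params
  st <- model$state
  if (length(dim(X)) == 2L) dim(X) <- c(dim(X), 1L)
  if (dim(X)[1] != cfg$n_regions * cfg$n_bands) {
    stop("input has ", dim(X)[1], " channels; expected ",
         cfg$n_regions * cfg$n_bands, call. = FALSE)
  }
  if (dim(X)[2] != cfg$input_samples) {
    stop("input has ", dim(X)[2], " samples; model was built for ",
         cfg$input_samples, call. = FALSE)
  }
  M <- cfg$n_temporal_maps
  Tw <- cfg$input_samples
  B <- dim(X)[3]
  ctr1 <- (cfg$temporal_kernel_len - 1L) %/% 2L
  ctr5 <- (cfg$separable_kernel_len - 1L) %/% 2L
  ii <- model$pair_index$pairs$i
  jj <- model$pair_index$pairs$j
  band_rows <- function(u) (seq_len(cfg$n_regions) - 1L) * cfg$n_bands + u

  c1 <- a1 <- bn1c <- r2 <- d2 <- vector("list", M)
  s4 <- bn4c <- e4 <- p4 <- m4 <- vector("list", M)
  T4 <- Tw %/% cfg$pool1
  A5 <- array(0, c(M, T4, B))
  ii0 <- as.integer(ii - 1L)
  jj0 <- as.integer(jj - 1L)
  for (m in seq_len(M)) {
    c1[[m]] <- tconv(X, p$k1[m, , drop = FALSE], ctr1, FALSE)
    bn <- bn_global_fwd(c1[[m]], p$bn1_g[m], p$bn1_b[m], st$bn1_rm[m],
                        st$bn1_rv[m], cfg$bn_momentum, cfg$bn_eps, training)
    st$bn1_rm[m] <- bn$rm; st$bn1_rv[m] <- bn$rv
    a1[[m]] <- bn$y; bn1c[[m]] <- bn$cache

    r2[[m]] <- nx_group_collapse_fwd(a1[[m]], p$w2[m, , ])
    d2[[m]] <- tconv(r2[[m]], p$k2[m, , ], ctr1, TRUE)

    s4m <- nx_interact_spatial_fwd(d2[[m]], p$w4[m, ], ii0, jj0)
    bn <- bn_global_fwd(s4m, p$bn4_g[m], p$bn4_b[m], st$bn4_rm[m],
                        st$bn4_rv[m], cfg$bn_momentum, cfg$bn_eps, training)
    st$bn4_rm[m] <- bn$rm; st$bn4_rv[m] <- bn$rv
    s4[[m]] <- s4m; bn4c[[m]] <- bn$cache
    e4[[m]] <- elu_fwd(bn$y)
    pooled <- pool_mat_fwd(e4[[m]], cfg$pool1)
    dr <- dropout_fwd(pooled, cfg$dropout_p, training)
    p4[[m]] <- pooled; m4[m] <- list(dr$mask)
    A5[m, , ] <- dr$y
  }

  d5 <- tconv(A5, p$k5, ctr5, TRUE)
  q5 <- array(p$p5 %*% matrix(d5, M), c(M, T4, B))
  bn5 <- bn_row_fwd(q5, p$bn5_g, p$bn5_b, st$bn5_rm, st$bn5_rv,
                    cfg$bn_momentum, cfg$bn_eps, training)
  st$bn5_rm <- bn5$rm; st$bn5_rv <- bn5$rv
  e5 <- elu_fwd(bn5$y)
  p5o <- pool_cube_fwd(e5, cfg$pool2)
  dr5 <- dropout_fwd(p5o, cfg$dropout_p, training)
  T5 <- T4 %/% cfg$pool2
  Fl <- matrix(dr5$y, M * T5, B)
  Z <- p$W6 %*% Fl
  probs <- softmax_cols(Z)

  model$state <- st
  out <- list(probs = probs, logits = Z, model = model)
  if (want_cache) {
    out$cache <- list(X = X, a1 = a1, bn1c = bn1c, r2 = r2, d2 = d2,
                      s4 = s4, bn4c = bn4c, e4 = e4, p4 = p4,
                      m4 = m4, A5 = A5, d5 = d5, bn5c = bn5$cache, e5 = e5,
                      m5 = dr5$mask, Fl = Fl, B = B)
  }
  if (return_stages) {
    i3 <- lapply(d2, function(d) {
      d[ii, , , drop = FALSE] * d[jj, , , drop = FALSE]
    })
    out$stages <- list(temporal_maps = c1, region_signals = d2,
                       interactions = i3, pooled = A5, features = Fl)
  }
  out
}

decoder_backward <- function(model, cache, dZ) {
  cfg <- model$config
  p <- model$params
  M <- cfg$n_temporal_maps
  Tw <- cfg$input_samples
  T4 <- Tw %/% cfg$pool1
  B <- cache$B
  ctr1 <- (cfg$temporal_kernel_len - 1L) %/% 2L
  ctr5 <- (cfg$separable_kernel_len - 1L) %/% 2L
  ii0 <- as.integer(model$pair_index$pairs$i - 1L)
  jj0 <- as.integer(model$pair_index$pairs$j - 1L)
  g <- lapply(p, function(x) x * 0)

  g$W6 <- dZ %*% t(cache$Fl)
  dFl <- t(p$W6) %*% dZ
  T5 <- T4 %/% cfg$pool2
  dz5 <- array(dFl, c(M, T5, B))
  if (!is.null(cache$m5)) dz5 <- dz5 * cache$m5
  de5 <- pool_cube_bwd(dz5, cfg$pool2, T4)
  dbn5 <- elu_bwd(de5, cache$e5)
  bn <- bn_row_bwd(dbn5, cache$bn5c, p$bn5_g)
  g$bn5_g <- bn$dgamma; g$bn5_b <- bn$dbeta
  dq5 <- bn$dx
  g$p5 <- matrix(dq5, M) %*% t(matrix(cache$d5, M))
  dd5 <- array(t(p$p5) %*% matrix(dq5, M), c(M, T4, B))
  g$k5 <- tconv_kgrad(cache$A5, dd5, ctr5, cfg$separable_kernel_len, TRUE)
  dA5 <- tconv_dx(dd5, p$k5, ctr5, TRUE)

  for (m in seq_len(M)) {
    dz4 <- matrix(dA5[m, , ], T4, B)
    if (!is.null(cache$m4[[m]])) dz4 <- dz4 * cache$m4[[m]]
    de4 <- pool_mat_bwd(dz4, cfg$pool1, Tw)
    dbn4 <- elu_bwd(de4, cache$e4[[m]])
    bn <- bn_global_bwd(dbn4, cache$bn4c[[m]], p$bn4_g[m])
    g$bn4_g[m] <- bn$dgamma; g$bn4_b[m] <- bn$dbeta
    ds4 <- bn$dx
    isb <- nx_interact_spatial_bwd(cache$d2[[m]], p$w4[m, ], ds4, ii0, jj0)
    g$w4[m, ] <- isb$dw4
    dd2 <- isb$dd2

    g$k2[m, , ] <- tconv_kgrad(cache$r2[[m]], dd2, ctr1,
                               cfg$temporal_kernel_len, TRUE)
    dr2 <- tconv_dx(dd2, p$k2[m, , ], ctr1, TRUE)
    gc2 <- nx_group_collapse_bwd(cache$a1[[m]], dr2, p$w2[m, , ])
    g$w2[m, , ] <- gc2$dw
    da1 <- gc2$da1
    bn <- bn_global_bwd(da1, cache$bn1c[[m]], p$bn1_g[m])
    g$bn1_g[m] <- bn$dgamma; g$bn1_b[m] <- bn$dbeta
    g$k1[m, ] <- tconv_kgrad(cache$X, bn$dx, ctr1,
                             cfg$temporal_kernel_len, FALSE)[1, ]
  }
  g
}

#' Class probabilities or labels for a window set
#'
#' Runs the decoder in evaluation mode (batch-normalization running
#' statistics, no dropout).
#'
#' @param object A `neurixn_decoder`.
#' @param windows A `window_set` or a `30 x T x B` array.
#' @param type "prob" for class probabilities, "class" for labels.
#' @param batch_size Evaluation batch size.
#' @param ... Unused.
#' @return A `B x 2` probability matrix (columns "left", "right") or a
#'   character vector of labels.
#' @export
predict.neurixn_decoder <- function(object, windows, type = c("prob", "class"),
                                    batch_size = 128, ...) {
  type <- match.arg(type)
  X <- if (inherits(windows, "window_set")) windows$data else windows
  if (length(dim(X)) == 2L) dim(X) <- c(dim(X), 1L)
  B <- dim(X)[3]
  probs <- matrix(0, B, object$config$n_classes)
  for (at in seq(1, B, by = batch_size)) {
    idx <- at:min(at + batch_size - 1, B)
    out <- decoder_forward(object, X[, , idx, drop = FALSE], training = FALSE)
    probs[idx, ] <- t(out$probs)
  }
  colnames(probs) <- class_levels()
  if (type == "prob") {
    probs
  } else {
    class_levels()[max.col(probs, ties.method = "first")]
  }
}

class_levels <- function() c("left", "right")
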