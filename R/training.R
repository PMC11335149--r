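# Optimization with validation stopping.  Cross-entropy loss, Adam
# (learning rate 1e-3, default moments), batch size 32, a fixed number of
# epochs; after every epoch the validation loss is recorded and at the end
# the parameters of the best-validation-loss epoch are restored.  After
# every optimizer step the spatial-filter rows are projected back onto the
# max-norm ball.  All shuffling and dropout randomness is seeded.

#' Train the interaction decoder on one cross-validation fold
#'
#' @param model A [build_decoder()] object.
#' @param split A `cv_split`.  For `scope == "within"` its id sets are trial
#'   ids; for `scope == "cross"` they are participant ids.
#' @param windows A `window_set` containing all windows of the fold's
#'   participant(s).
#' @param epochs Number of training epochs (the study protocol uses 200).
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate.
#' @param seed Integer seed controlling batch shuffling and dropout;
#'   identical seeds on an identically initialized model give identical
#'   validation-loss curves.
#' @param participant_id Provenance tag for the report.
#' @return A `train_report`: list with `model` (parameters of the best
#'   validation epoch), `best_epoch`, `val_loss_curve`, `train_loss_curve`,
#'   `test_accuracy`, `fold_id`, `participant_id`, `seed`.
#' @export
train_decoder <- function(model, split, windows, epochs = 200,
                          batch_size = 32, lr = 1e-3, seed = 1,
                          participant_id = NA) {
  sets <- split_window_sets(split, windows)
  if (!length(sets$train) || !length(sets$val) || !length(sets$test)) {
    stop("infeasible split: empty train/val/test window set", call. = FALSE)
  }
  cfg <- model$config
  ytr <- label_onehot(sets$train$meta$label, cfg$n_classes)
  yva <- label_onehot(sets$val$meta$label, cfg$n_classes)
  n_train <- length(sets$train)

  set.seed(seed)
  opt <- adam_init(model$params)
  val_curve <- train_curve <- numeric(epochs)
  best <- list(loss = Inf, params = model$params, state = model$state,
               epoch = 0L)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n_train)
    ep_loss <- 0
    n_batches <- 0L
    for (at in seq(1, n_train, by = batch_size)) {
      idx <- ord[at:min(at + batch_size - 1, n_train)]
      Xb <- sets$train$data[, , idx, drop = FALSE]
      Yb <- ytr[, idx, drop = FALSE]
      fwd <- decoder_forward(model, Xb, training = TRUE, want_cache = TRUE)
      model <- fwd$model
      ep_loss <- ep_loss + cross_entropy(fwd$probs, Yb)
      n_batches <- n_batches + 1L
      dZ <- (fwd$probs - Yb) / ncol(Yb)
      grads <- decoder_backward(model, fwd$cache, dZ)
      stepped <- adam_step(model$params, grads, opt, lr = lr)
      model$params <- stepped$params
      opt <- stepped$state
      model$params$w4 <- maxnorm_project_rows(model$params$w4, cfg$maxnorm)
    }
    train_curve[ep] <- ep_loss / n_batches
    val_curve[ep] <- batched_loss(model, sets$val$data, yva)
    if (val_curve[ep] < best$loss) {
      best <- list(loss = val_curve[ep], params = model$params,
                   state = model$state, epoch = ep)
    }
  }
  model$params <- best$params
  model$state <- best$state
  structure(list(model = model, best_epoch = best$epoch,
                 val_loss_curve = val_curve, train_loss_curve = train_curve,
                 test_accuracy = evaluate_accuracy(model, sets$test),
                 fold_id = split$fold_id, participant_id = participant_id,
                 seed = seed),
            class = "train_report")
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf(
    "<train_report> fold %s: best epoch %d/%d (val loss %.4f), test accuracy %.3f\n",
    format(x$fold_id), x$best_epoch, length(x$val_loss_curve),
    min(x$val_loss_curve), x$test_accuracy))
  invisible(x)
}

split_window_sets <- function(split, windows) {
  if (split$scope == "within") {
    list(train = subset_windows(windows, trial_ids = split$train_ids),
         val = subset_windows(windows, trial_ids = split$val_ids),
         test = subset_windows(windows, trial_ids = split$test_ids))
  } else {
    list(train = subset_windows(windows, participant_ids = split$train_ids),
         val = subset_windows(windows, participant_ids = split$val_ids),
         test = subset_windows(windows, participant_ids = split$test_ids))
  }
}

label_onehot <- function(labels, n_classes = 2) {
  lv <- class_levels()
  idx <- match(labels, lv)
  if (anyNA(idx)) stop("labels must be in {left, right}", call. = FALSE)
  y <- matrix(0, n_classes, length(idx))
  y[cbind(idx, seq_along(idx))] <- 1
  y
}

batched_loss <- function(model, X, y_onehot, batch_size = 128) {
  B <- dim(X)[3]
  total <- 0
  for (at in seq(1, B, by = batch_size)) {
    idx <- at:min(at + batch_size - 1, B)
    out <- decoder_forward(model, X[, , idx, drop = FALSE], training = FALSE)
    total <- total + cross_entropy(out$probs,
                                   y_onehot[, idx, drop = FALSE]) * length(idx)
  }
  total / B
}

#' Decoding accuracy on a window set
#'
#' Fraction of windows whose maximum-probability class equals the label.
#'
#' @param model A `neurixn_decoder`.
#' @param windows A `window_set` with at least one window.
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_accuracy <- function(model, windows) {
  stopifnot(length(windows) >= 1)
  pred <- predict(model, windows, type = "class")
  mean(pred == windows$meta$label)
}
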