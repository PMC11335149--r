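# Sliding-window construction.  A window set stores the window tensor
# (channels x T x n_windows) plus one metadata row per window; every window
# cut from a trial inherits the trial's label, condition and block id, so
# block-wise splits can never leak half-overlapping windows across folds.

new_window_set <- function(data, meta, fs, chan_index) {
  stopifnot(length(dim(data)) == 3L, nrow(meta) == dim(data)[3])
  structure(list(data = data, meta = meta, fs = fs,
                 channel_index = chan_index),
            class = "window_set")
}

#' Number of windows in a window set
#' @param x A `window_set`.
#' @export
length.window_set <- function(x) dim(x$data)[3]

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<window_set> %d windows of %d x %d (fs %g Hz)\n",
              d[3], d[1], d[2], x$fs))
  invisible(x)
}

#' Cut sliding windows from an enhanced trial
#'
#' Windows of `window_seconds` start every
#' `round((1 - overlap_fraction) * T)` samples; only windows fully inside the
#' trial are kept (a final partial window is dropped, no padding).  Each
#' window inherits the trial's label, condition, trial id and block id.
#'
#' @param trial An [enhanced_trial()].
#' @param window_seconds Window length in seconds.
#' @param overlap_fraction Fraction of overlap between consecutive windows,
#'   in `[0, 1)`; the study design uses 0.5.
#' @param block_id Block identifier carried by every window (default `NA`).
#' @param participant_id Participant identifier carried by every window.
#' @return A `window_set`; zero windows (with a warning) if the trial is
#'   shorter than the window.
#' @export
sliding_windows <- function(trial, window_seconds, overlap_fraction = 0.5,
                            block_id = NA_integer_,
                            participant_id = NA_character_) {
  stopifnot(inherits(trial, "enhanced_trial"),
            overlap_fraction >= 0, overlap_fraction < 1)
  T_win <- as.integer(round(window_seconds * trial$fs))
  T_trial <- ncol(trial$data)
  step <- max(1L, as.integer(round((1 - overlap_fraction) * T_win)))
  if (T_win > T_trial) {
    warning("window (", T_win, " samples) longer than trial (", T_trial,
            "); returning no windows")
    starts <- integer(0)
  } else {
    starts <- seq.int(1L, T_trial - T_win + 1L, by = step)
  }
  n <- length(starts)
  data <- array(0, dim = c(nrow(trial$data), T_win, n))
  for (k in seq_len(n)) {
    data[, , k] <- trial$data[, starts[k]:(starts[k] + T_win - 1L)]
  }
  meta <- data.frame(
    label = rep(trial$label, n), trial_id = rep(trial$trial_id, n),
    block_id = rep(block_id, n), participant_id = rep(participant_id, n),
    start = starts, stringsAsFactors = FALSE)
  new_window_set(data, meta, trial$fs, trial$channel_index)
}

#' Concatenate window sets
#'
#' @param ... `window_set` objects sharing window length and channel layout.
#' @return A single `window_set`.
#' @export
bind_windows <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "window_set")) {
    sets <- sets[[1]]
  }
  stopifnot(length(sets) >= 1L)
  dims <- vapply(sets, function(s) dim(s$data)[1:2], numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("window sets have incompatible shapes", call. = FALSE)
  }
  n <- sum(vapply(sets, function(s) dim(s$data)[3], numeric(1)))
  data <- array(0, dim = c(dims[1, 1], dims[2, 1], n))
  at <- 0L
  for (s in sets) {
    k <- dim(s$data)[3]
    if (k > 0) data[, , at + seq_len(k)] <- s$data
    at <- at + k
  }
  meta <- do.call(rbind, lapply(sets, `[[`, "meta"))
  rownames(meta) <- NULL
  new_window_set(data, meta, sets[[1]]$fs, sets[[1]]$channel_index)
}

#' Subset a window set
#'
#' @param windows A `window_set`.
#' @param idx Window indices, or `NULL` with `trial_ids` /
#'   `participant_ids` selecting by metadata.
#' @param trial_ids,participant_ids Optional metadata filters.
#' @return A `window_set`.
#' @export
subset_windows <- function(windows, idx = NULL, trial_ids = NULL,
                           participant_ids = NULL) {
  stopifnot(inherits(windows, "window_set"))
  if (is.null(idx)) {
    keep <- rep(TRUE, length(windows))
    if (!is.null(trial_ids)) keep <- keep & windows$meta$trial_id %in% trial_ids
    if (!is.null(participant_ids)) {
      keep <- keep & windows$meta$participant_id %in% participant_ids
    }
    idx <- which(keep)
  }
  new_window_set(windows$data[, , idx, drop = FALSE],
                 windows$meta[idx, , drop = FALSE],
                 windows$fs, windows$channel_index)
}
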