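# Cross-validation protocols.  Within-participant: trials are assigned to
# four blocks by condition-and-label stratified shuffling, and each fold uses
# two blocks for training, one for validation and one for testing, rotating
# the test block.  Because every window of a trial carries the trial's block
# id, no 50%-overlapping window can straddle a partition boundary.
# Cross-participant: each participant is the test set in `n_repeats`
# iterations with a fresh random validation group each time.

new_cv_split <- function(fold_id, train_ids, val_ids, test_ids, scope,
                         block_of = NULL) {
  stopifnot(scope %in% c("within", "cross"))
  if (length(intersect(train_ids, val_ids)) ||
      length(intersect(train_ids, test_ids)) ||
      length(intersect(val_ids, test_ids))) {
    stop("split sets are not disjoint", call. = FALSE)
  }
  structure(list(fold_id = fold_id, train_ids = train_ids, val_ids = val_ids,
                 test_ids = test_ids, scope = scope, block_of = block_of),
            class = "cv_split")
}

#' Block-wise within-participant cross-validation splits
#'
#' Assigns trials to `n_blocks` blocks by stratified shuffling so that every
#' block receives an (as near as possible) equal share of each
#' condition-by-label stratum, then forms `n_blocks` folds: in fold `f` the
#' test set is block `f`, the validation set the next block (cyclically) and
#' the remaining two blocks the training set.
#'
#' @param trials A [region_trial_set()].
#' @param n_blocks Number of blocks (the study design uses 4).
#' @param seed Integer seed; identical seeds give identical assignments.
#' @return List of `cv_split` objects (one per fold) whose id sets are trial
#'   indices; each carries `block_of`, the trial-to-block assignment.
#' @export
make_within_splits <- function(trials, n_blocks = 4, seed = 1) {
  stopifnot(inherits(trials, "region_trial_set"))
  n <- length(trials$trials)
  if (n < n_blocks) {
    stop("infeasible split: fewer trials (", n, ") than blocks (", n_blocks,
         ")", call. = FALSE)
  }
  strata <- interaction(trials$conditions, trials$labels, drop = TRUE)
  block_of <- integer(n)
  set.seed(seed)
  # per-block bookkeeping so remainders even out within each condition and
  # each label, not just in total
  cond_count <- matrix(0L, n_blocks, length(unique(trials$conditions)),
                       dimnames = list(NULL, sort(unique(trials$conditions))))
  lab_count <- matrix(0L, n_blocks, 2, dimnames = list(NULL,
                                                       c("left", "right")))
  for (s in levels(strata)) {
    ids <- sample(which(strata == s))
    cond <- trials$conditions[ids[1]]
    lab <- trials$labels[ids[1]]
    base <- length(ids) %/% n_blocks
    rem <- length(ids) - base * n_blocks
    # blocks with the fewest trials of this condition (then label) get the
    # remainder; random tie-break
    pref <- order(cond_count[, cond], lab_count[, lab],
                  stats::runif(n_blocks))
    counts <- rep(base, n_blocks)
    if (rem > 0) counts[pref[seq_len(rem)]] <- base + 1L
    blocks <- rep(seq_len(n_blocks), counts)
    block_of[ids] <- blocks
    for (b in seq_len(n_blocks)) {
      cond_count[b, cond] <- cond_count[b, cond] + counts[b]
      lab_count[b, lab] <- lab_count[b, lab] + counts[b]
    }
  }
  lapply(seq_len(n_blocks), function(f) {
    test_b <- f
    val_b <- (f %% n_blocks) + 1L
    train_b <- setdiff(seq_len(n_blocks), c(test_b, val_b))
    new_cv_split(
      fold_id = f,
      train_ids = which(block_of %in% train_b),
      val_ids = which(block_of == val_b),
      test_ids = which(block_of == test_b),
      scope = "within", block_of = block_of)
  })
}

#' Cross-participant cross-validation splits
#'
#' For each participant `p` and each of `n_repeats` iterations, the test set
#' is `{p}`, the validation set `n_val` other participants drawn at random,
#' and the training set the rest.  With 18 participants, `n_val = 4` and
#' `n_repeats = 5` this yields the 90-fold scheme with 13 training
#' participants per fold.
#'
#' @param participant_ids Character vector of participant identifiers.
#' @param n_val Validation-set size; must satisfy
#'   `n_val < length(participant_ids) - 1`.
#' @param n_repeats Iterations per participant.
#' @param seed Integer seed.
#' @return List of `n_participants * n_repeats` `cv_split` objects whose id
#'   sets are participant identifiers.
#' @export
make_cross_splits <- function(participant_ids, n_val, n_repeats = 5,
                              seed = 1) {
  n <- length(participant_ids)
  if (!(n_val < n - 1)) {
    stop("n_val must be smaller than n_participants - 1", call. = FALSE)
  }
  set.seed(seed)
  folds <- list()
  fold_id <- 0L
  for (p in participant_ids) {
    others <- setdiff(participant_ids, p)
    for (r in seq_len(n_repeats)) {
      fold_id <- fold_id + 1L
      val <- if (n_val > 0) sample(others, n_val) else character(0)
      folds[[fold_id]] <- new_cv_split(
        fold_id = fold_id,
        train_ids = setdiff(others, val), val_ids = val, test_ids = p,
        scope = "cross")
    }
  }
  folds
}
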