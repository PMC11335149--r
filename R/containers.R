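#' Per-participant region-level trial container
#'
#' Bundles one participant's trials, where each trial maps the ten region
#' codes to a sources-by-samples matrix of source-space signal amplitudes,
#' together with the sampling rate, the per-trial attention labels
#' ("left"/"right") and condition tags.
#'
#' @param participant_id Character scalar.
#' @param trials List of trials; each trial is a named list of
#'   `n_sources x n_samples` numeric matrices, one per region code.
#' @param fs Sampling rate in Hz.
#' @param labels Character vector, one of "left"/"right" per trial.
#' @param conditions Character (or factor) vector, one tag per trial.
#' @param region_order Region codes; defaults to the canonical ten.
#' @return An object of class `region_trial_set`.
#' @export
region_trial_set <- function(participant_id, trials, fs, labels, conditions,
                             region_order = canonical_region_order()) {
  if (length(region_order) != 10L || anyDuplicated(region_order) ||
      !setequal(region_order, canonical_region_order())) {
    stop("invalid region order: expected the 10 canonical region codes",
         call. = FALSE)
  }
  n_trials <- length(trials)
  stopifnot(length(labels) == n_trials, length(conditions) == n_trials,
            is.numeric(fs), fs > 0)
  if (!all(labels %in% c("left", "right"))) {
    stop("labels must be 'left' or 'right'", call. = FALSE)
  }
  n_sources <- NULL
  for (k in seq_len(n_trials)) {
    tr <- trials[[k]]
    if (!setequal(names(tr), region_order)) {
      stop("trial ", k, ": regions do not match region_order", call. = FALSE)
    }
    ns <- vapply(tr[region_order], nrow, integer(1))
    if (is.null(n_sources)) n_sources <- ns
    if (!identical(unname(ns), unname(n_sources))) {
      stop("trial ", k, ": per-region source counts differ across trials",
           call. = FALSE)
    }
    nt <- vapply(tr[region_order], ncol, integer(1))
    if (length(unique(nt)) != 1L) {
      stop("trial ", k, ": regions have unequal sample counts", call. = FALSE)
    }
  }
  structure(list(participant_id = as.character(participant_id),
                 trials = trials, fs = fs,
                 labels = as.character(labels),
                 conditions = as.character(conditions),
                 region_order = region_order),
            class = "region_trial_set")
}

#' @export
print.region_trial_set <- function(x, ...) {
  ns <- if (length(x$trials)) ncol(x$trials[[1]][[x$region_order[1]]]) else 0L
  cat(sprintf(
    "<region_trial_set> participant %s: %d trials, fs %g Hz, %d samples/trial (first trial)\n",
    x$participant_id, length(x$trials), x$fs, ns))
  cat("  labels:", paste(sprintf("%s=%d", names(table(x$labels)),
                                 table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of trials in a region trial set
#' @param x A `region_trial_set`.
#' @param ... Unused.
#' @export
length.region_trial_set <- function(x) length(x$trials)

#' Band-enhanced trial representation
#'
#' The 30 x T representation of one trial: per region and band, one
#' GED-enhanced component time course, region-major / band-minor.
#'
#' @param data 30 x T numeric matrix.
#' @param fs Sampling rate in Hz.
#' @param label Attention label ("left"/"right").
#' @param condition Condition tag.
#' @param trial_id Integer trial identifier.
#' @param chan_index Channel index as from [channel_index()].
#' @return An object of class `enhanced_trial`.
#' @export
enhanced_trial <- function(data, fs, label, condition, trial_id,
                           chan_index = channel_index()) {
  stopifnot(is.matrix(data), nrow(data) == nrow(chan_index))
  structure(list(data = data, channel_index = chan_index, fs = fs,
                 label = label, condition = condition, trial_id = trial_id),
            class = "enhanced_trial")
}

# --- on-disk container -----------------------------------------------------
# One RDS file with the trial matrices plus a JSON sidecar carrying the
# metadata (fs, labels, conditions, region order), one pair of files per
# participant.

#' Write a region trial set to disk
#'
#' Writes `<dir>/<participant_id>.rds` (trial matrices) and
#' `<dir>/<participant_id>.json` (metadata sidecar).
#'
#' @param x A `region_trial_set`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_region_trials <- function(x, dir) {
  stopifnot(inherits(x, "region_trial_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rds <- file.path(dir, paste0(x$participant_id, ".rds"))
  json <- file.path(dir, paste0(x$participant_id, ".json"))
  saveRDS(x$trials, rds)
  meta <- list(participant_id = x$participant_id, fs = x$fs,
               labels = x$labels, conditions = x$conditions,
               region_order = x$region_order, n_trials = length(x$trials))
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA)
  invisible(c(rds = rds, json = json))
}

#' Read a region trial set from disk
#'
#' @param dir Directory holding the container.
#' @param participant_id Participant identifier (file stem).
#' @return A `region_trial_set`.
#' @export
read_region_trials <- function(dir, participant_id) {
  trials <- readRDS(file.path(dir, paste0(participant_id, ".rds")))
  meta <- jsonlite::read_json(file.path(dir, paste0(participant_id, ".json")),
                              simplifyVector = TRUE)
  region_trial_set(meta$participant_id, trials, meta$fs, meta$labels,
                   meta$conditions, meta$region_order)
}
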