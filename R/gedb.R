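# Generalized-eigendecomposition band enhancement (GEDb).  For each region
# and band, the covariance of band-pass-filtered source signals (signal
# covariance S) is contrasted against the shrinkage-regularized broadband
# covariance (reference R) by solving S w = lambda R w.  The eigenvector of
# the largest eigenvalue maximizes the band-to-broadband power ratio; only
# this first component is retained, and its weights are applied to the
# *broadband* sources so that all frequencies survive into the enhanced
# channels (the bands shape the objective, not the output spectrum - the
# band-removal retests rely on this).

#' Zero-phase Butterworth band-pass filter
#'
#' Order-4 Butterworth band-pass applied forward and backward
#' (zero-phase) to each row of a channels-by-samples matrix.
#'
#' @param x Numeric matrix (channels x samples) or vector.
#' @param low_hz,high_hz Band edges in Hz; `0 < low_hz < high_hz <= fs/2`.
#'   A band whose upper edge reaches the Nyquist frequency (e.g. beta,
#'   15-32 Hz at 64 Hz) degenerates to a high-pass at `low_hz` (or, for
#'   `type = "stop"`, a low-pass at `low_hz`).
#' @param fs Sampling rate in Hz.
#' @param order Butterworth order (default 4).
#' @param type "pass" (default) or "stop".
#' @return Filtered object of the same shape.
#' @export
bandpass_filter <- function(x, low_hz, high_hz, fs, order = 4,
                            type = c("pass", "stop")) {
  type <- match.arg(type)
  if (!(low_hz > 0 && high_hz > low_hz && high_hz <= fs / 2)) {
    stop("invalid band: need 0 < low < high <= fs/2", call. = FALSE)
  }
  bf <- if (high_hz >= (fs / 2) * (1 - 1e-9)) {
    signal::butter(order, low_hz / (fs / 2),
                   type = if (type == "pass") "high" else "low")
  } else {
    signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = type)
  }
  if (is.matrix(x)) {
    nx_filtfilt_mat(bf$b, bf$a, x)
  } else {
    as.vector(nx_filtfilt(bf$b, bf$a, x))
  }
}

#' First GED band-enhancement component
#'
#' Solves the generalized eigenproblem `S w = lambda R w`, where `S` is the
#' covariance of the band-filtered sources and `R` the shrinkage-regularized
#' broadband covariance, and returns the eigenvector of the largest
#' eigenvalue, unit-normalized with its largest-magnitude weight positive.
#' `cov_signal`/`cov_reference` can be supplied directly (e.g. averaged over
#' training trials), bypassing the filtering step.
#'
#' @param sources Numeric matrix (n_sources x n_samples).
#' @param band A [band_spec()].
#' @param fs Sampling rate in Hz.
#' @param shrinkage Shrinkage of the reference covariance toward the scaled
#'   identity, in `[0, 1)`; default 0.01 guards the solve against rank
#'   deficiency.
#' @param cov_signal,cov_reference Optional precomputed covariances.
#' @return A `ged_component`: list with `weights`, `eigenvalue`,
#'   `band_code`, `region_code`.
#' @export
gedb_first_component <- function(sources = NULL, band, fs,
                                 shrinkage = 0.01,
                                 cov_signal = NULL, cov_reference = NULL) {
  stopifnot(shrinkage >= 0, shrinkage < 1)
  if (is.null(cov_signal) || is.null(cov_reference)) {
    stopifnot(is.matrix(sources), ncol(sources) > nrow(sources))
    xf <- bandpass_filter(sources, band$low_hz, band$high_hz, fs)
    cov_signal <- row_cov(xf)
    cov_reference <- row_cov(sources)
  }
  R <- regularize_cov(cov_reference, shrinkage)
  U <- tryCatch(chol(R), error = function(e) {
    stop("singular reference covariance (after shrinkage ", shrinkage, ")",
         call. = FALSE)
  })
  # whiten: M = U^-T S U^-1, symmetric; top eigenvector y -> w = U^-1 y
  A <- backsolve(U, cov_signal, transpose = TRUE)       # U^-T S
  M <- t(backsolve(U, t(A), transpose = TRUE))          # U^-T S U^-1
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  w <- backsolve(U, e$vectors[, 1])
  w <- fix_sign(w / sqrt(sum(w^2)))
  structure(list(weights = w, eigenvalue = e$values[1],
                 band_code = band$band_code, region_code = NA_character_),
            class = "ged_component")
}

row_cov <- function(x) {
  xc <- x - rowMeans(x)
  tcrossprod(xc) / (ncol(x) - 1)
}

regularize_cov <- function(R, shrinkage) {
  if (shrinkage <= 0) return(R)
  (1 - shrinkage) * R + shrinkage * mean(diag(R)) * diag(nrow(R))
}

fix_sign <- function(w) {
  if (all(w == 0) || any(!is.finite(w))) {
    stop("degenerate component weights", call. = FALSE)
  }
  w * sign(w[which.max(abs(w))])
}

#' Fit GED components for one participant
#'
#' Per-trial signal and reference covariances are averaged across the given
#' trials (typically the training blocks of a fold, so that no test-set
#' statistics leak into the enhancement) before one eigendecomposition per
#' region and band.
#'
#' @param trials A [region_trial_set()].
#' @param trial_ids Trials to estimate covariances from (default: all).
#' @param bands List of [band_spec()]s; defaults to [canonical_bands()].
#' @param shrinkage Reference-covariance shrinkage (see
#'   [gedb_first_component()]).
#' @return Nested list `components[[region]][[band]]` of `ged_component`s.
#' @export
fit_gedb_components <- function(trials, trial_ids = NULL,
                                bands = canonical_bands(), shrinkage = 0.01) {
  stopifnot(inherits(trials, "region_trial_set"))
  if (is.null(trial_ids)) trial_ids <- seq_along(trials$trials)
  comps <- list()
  for (region in trials$region_order) {
    n_src <- nrow(trials$trials[[trial_ids[1]]][[region]])
    Ssum <- lapply(bands, function(b) matrix(0, n_src, n_src))
    Rsum <- matrix(0, n_src, n_src)
    for (k in trial_ids) {
      x <- trials$trials[[k]][[region]]
      Rsum <- Rsum + row_cov(x)
      for (bn in names(bands)) {
        b <- bands[[bn]]
        xf <- bandpass_filter(x, b$low_hz, b$high_hz, trials$fs)
        Ssum[[bn]] <- Ssum[[bn]] + row_cov(xf)
      }
    }
    nt <- length(trial_ids)
    comps[[region]] <- lapply(names(bands), function(bn) {
      cmp <- gedb_first_component(band = bands[[bn]], fs = trials$fs,
                                  shrinkage = shrinkage,
                                  cov_signal = Ssum[[bn]] / nt,
                                  cov_reference = Rsum / nt)
      cmp$region_code <- region
      cmp
    })
    names(comps[[region]]) <- names(bands)
  }
  comps
}

#' Band-enhance one trial to the 30-channel representation
#'
#' Applies each region's per-band component weights to that region's
#' unfiltered (broadband) source matrix, producing 3 enhanced channels per
#' region in canonical region-major / band-minor order; every channel is
#' standardized to zero mean and unit variance (the scale of a unit-norm
#' eigenvector is arbitrary, so channels are brought to a common scale).
#'
#' @param trial_sources Named list mapping region codes to source matrices.
#' @param bands List of [band_spec()]s (canonical order).
#' @param fs Sampling rate in Hz.
#' @param components Pre-fitted components from [fit_gedb_components()];
#'   if `NULL`, components are fitted on this trial alone.
#' @param label,condition,trial_id Metadata carried into the result.
#' @param shrinkage Shrinkage used when fitting on the fly.
#' @return An [enhanced_trial()].
#' @export
enhance_trial <- function(trial_sources, bands = canonical_bands(), fs = 64,
                          components = NULL, label = NA, condition = NA,
                          trial_id = NA_integer_, shrinkage = 0.01) {
  regions <- canonical_region_order()
  missing <- setdiff(regions, names(trial_sources))
  if (length(missing)) {
    stop("invalid region set: missing ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  T_trial <- ncol(trial_sources[[regions[1]]])
  out <- matrix(0, length(regions) * length(bands), T_trial)
  row <- 0L
  for (region in regions) {
    x <- trial_sources[[region]]
    for (bn in names(bands)) {
      row <- row + 1L
      cmp <- if (is.null(components)) {
        gedb_first_component(x, bands[[bn]], fs, shrinkage)
      } else {
        components[[region]][[bn]]
      }
      ch <- as.vector(crossprod(cmp$weights, x))
      ch <- ch - mean(ch)
      s <- stats::sd(ch)
      out[row, ] <- if (s > 0) ch / s else ch
    }
  }
  enhanced_trial(out, fs, label, condition, trial_id,
                 channel_index(regions, names(bands)))
}

#' Band-enhance all trials of a participant
#'
#' @param trials A [region_trial_set()].
#' @param components Components from [fit_gedb_components()].
#' @param bands List of [band_spec()]s.
#' @return List of [enhanced_trial()]s, one per trial.
#' @export
enhance_participant <- function(trials, components,
                                bands = canonical_bands()) {
  stopifnot(inherits(trials, "region_trial_set"))
  lapply(seq_along(trials$trials), function(k) {
    enhance_trial(trials$trials[[k]], bands, trials$fs, components,
                  label = trials$labels[k], condition = trials$conditions[k],
                  trial_id = k)
  })
}
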