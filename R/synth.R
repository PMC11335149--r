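# Synthetic region-level datasets with planted, class-dependent structure.
# Each region source is a mixture of (a) 1/f pink background noise, (b)
# band-limited oscillations (filtered white noise, not sinusoids, so GED
# covariances are well conditioned) whose amplitudes implement a
# class-dependent lateralization (e.g. attending left raises right-parietal
# alpha power), and (c) for each planted pair, a shared band-limited
# oscillation modulated by a shared slow (< 1 Hz) envelope, added to both
# regions in one class only - a coherent, co-modulated component that the
# decoder's pairwise-product channels can express directly.

#' Specification of a synthetic attention dataset
#'
#' Defaults emulate the reference recording layout: 50-s trials at 64 Hz,
#' two balanced attention classes, three condition tags carrying no signal
#' (they exist to exercise stratification), with one planted RP-LP
#' alpha-band coupling in the attend-left class and a parietal alpha
#' lateralization of power ratio 2.
#'
#' @param n_participants,n_trials Dataset size (defaults 4 and 24).
#' @param trial_seconds,fs Trial length (s) and sampling rate (Hz).
#' @param n_sources_per_roi Sources per region.
#' @param planted_pairs List of planted couplings; each a list with
#'   `region_i`, `region_j`, `band` (canonical band code),
#'   `coupling` (amplitude of the shared component, >= 0) and
#'   `coupled_class` ("left"/"right").
#' @param lateralization List with `regions`, `band`, `power_ratio`: regions
#'   in the set lying contralateral to the attended side get their band
#'   power multiplied by `power_ratio`.
#' @param band_amplitude Named amplitudes (SD units) of the background
#'   band-limited oscillations, relative to the pink-noise SD; the default
#'   0.5 makes each narrowband rhythm a minority of the broadband power, so
#'   a unit-amplitude planted coupling stands clearly above the background.
#' @param envelope_depth Relative depth of the shared slow envelope.
#' @param noise_sd SD of the per-source pink noise.
#' @param condition_count Number of condition tags (round-robin).
#' @param seed Integer master seed.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_participants = 4, n_trials = 24,
                           trial_seconds = 50, fs = 64,
                           n_sources_per_roi = 2,
                           planted_pairs = list(list(
                             region_i = "RP", region_j = "LP",
                             band = "alpha", coupling = 1.0,
                             coupled_class = "left")),
                           lateralization = list(
                             regions = c("LP", "RP"), band = "alpha",
                             power_ratio = 2),
                           band_amplitude = c(delta_theta = 0.5, alpha = 0.5,
                                              beta = 0.5),
                           envelope_depth = 0.5, noise_sd = 1,
                           condition_count = 3, seed = 1) {
  for (pp in planted_pairs) {
    if (!all(c(pp$region_i, pp$region_j) %in% canonical_region_order()) ||
        !pp$band %in% canonical_band_order()) {
      stop("invalid region or band code in planted pair", call. = FALSE)
    }
    stopifnot(pp$coupling >= 0)
  }
  if (!is.null(lateralization)) {
    stopifnot(all(lateralization$regions %in% canonical_region_order()),
              lateralization$band %in% canonical_band_order(),
              lateralization$power_ratio > 0)
  }
  structure(list(n_participants = n_participants, n_trials = n_trials,
                 trial_seconds = trial_seconds, fs = fs,
                 n_sources_per_roi = n_sources_per_roi,
                 planted_pairs = planted_pairs,
                 lateralization = lateralization,
                 band_amplitude = band_amplitude,
                 envelope_depth = envelope_depth, noise_sd = noise_sd,
                 condition_count = condition_count, seed = seed),
            class = "generator_spec")
}

pink_noise <- function(n) {
  X <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)              # symmetric |frequency| index
  X <- X / sqrt(f)
  X[1] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / stats::sd(x)
}

band_limited_noise <- function(n, band, fs) {
  x <- bandpass_filter(stats::rnorm(n), band$low_hz, band$high_hz, fs)
  x / stats::sd(x)
}

slow_envelope <- function(n, fs, depth, cutoff_hz = 0.7) {
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  z <- as.vector(nx_filtfilt(bf$b, bf$a, stats::rnorm(n)))
  pmax(0, 1 + depth * z / stats::sd(z))
}

#' Generate a synthetic attention dataset
#'
#' @param spec A [generator_spec()].
#' @return List with `participants` (list of [region_trial_set()]s) and
#'   `ground_truth` (planted pairs, lateralization, per-participant labels).
#' @export
generate_attention_dataset <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  pseeds <- sample.int(.Machine$integer.max - 1L, spec$n_participants)
  bands <- canonical_bands()
  participants <- vector("list", spec$n_participants)
  truth_labels <- vector("list", spec$n_participants)
  for (p in seq_len(spec$n_participants)) {
    set.seed(pseeds[p])
    n_tr <- spec$n_trials
    labels <- sample(rep(c("left", "right"), length.out = n_tr))
    conditions <- rep(paste0("C", seq_len(spec$condition_count)),
                      length.out = n_tr)
    n <- round(spec$trial_seconds * spec$fs)
    trials <- vector("list", n_tr)
    for (k in seq_len(n_tr)) {
      base <- lapply(canonical_region_order(), function(r) numeric(n))
      names(base) <- canonical_region_order()
      for (r in canonical_region_order()) {
        for (bn in names(bands)) {
          amp <- spec$band_amplitude[[bn]] *
            sqrt(lateralization_gain(spec$lateralization, r, bn, labels[k]))
          if (amp > 0) {
            base[[r]] <- base[[r]] + amp * band_limited_noise(n, bands[[bn]],
                                                              spec$fs)
          }
        }
      }
      for (pp in spec$planted_pairs) {
        if (pp$coupling > 0 && identical(labels[k], pp$coupled_class)) {
          shared <- pp$coupling *
            slow_envelope(n, spec$fs, spec$envelope_depth) *
            band_limited_noise(n, bands[[pp$band]], spec$fs)
          base[[pp$region_i]] <- base[[pp$region_i]] + shared
          base[[pp$region_j]] <- base[[pp$region_j]] + shared
        }
      }
      trials[[k]] <- lapply(base, function(sig) {
        t(vapply(seq_len(spec$n_sources_per_roi), function(s) {
          stats::runif(1, 0.5, 1.5) * sig + spec$noise_sd * pink_noise(n)
        }, numeric(n)))
      })
    }
    participants[[p]] <- region_trial_set(
      participant_id = sprintf("S%02d", p), trials = trials, fs = spec$fs,
      labels = labels, conditions = conditions)
    truth_labels[[p]] <- labels
  }
  names(truth_labels) <- vapply(participants, `[[`, character(1),
                                "participant_id")
  list(participants = participants,
       ground_truth = list(planted_pairs = spec$planted_pairs,
                           lateralization = spec$lateralization,
                           labels = truth_labels, participant_seeds = pseeds))
}

lateralization_gain <- function(lat, region, band, label) {
  if (is.null(lat) || !identical(band, lat$band) ||
      !(region %in% lat$regions)) {
    return(1)
  }
  # contralateral organization: attending left raises right-hemisphere power
  contralateral <- (label == "left") == (region_hemisphere(region) == "right")
  if (contralateral) lat$power_ratio else 1
}

analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Diagnostic summary of a region trial set
#'
#' Per trial and region: band power of the region's mean source signal in
#' each canonical band; plus, per trial and band, the pairwise correlations
#' of Hilbert amplitude envelopes of the band-filtered region signals.
#'
#' @param trials A [region_trial_set()].
#' @param bands Named list of [band_spec()]s (default canonical).
#' @param pairs Optional [make_pair_index()] restriction of the envelope
#'   correlations.
#' @return List of two data frames, `band_power` and `envelope_corr`.
#' @export
summarize_dataset <- function(trials, bands = canonical_bands(),
                              pairs = make_pair_index()) {
  stopifnot(inherits(trials, "region_trial_set"), length(trials$trials) >= 1)
  regions <- trials$region_order
  bp <- list()
  ec <- list()
  for (k in seq_along(trials$trials)) {
    sig <- vapply(regions, function(r) colMeans(trials$trials[[k]][[r]]),
                  numeric(ncol(trials$trials[[k]][[regions[1]]])))
    for (bn in names(bands)) {
      b <- bands[[bn]]
      filt <- apply(sig, 2, function(v) {
        bandpass_filter(v, b$low_hz, b$high_hz, trials$fs)
      })
      bp[[length(bp) + 1L]] <- data.frame(
        trial = k, label = trials$labels[k], region = regions,
        band = bn, power = apply(filt, 2, stats::var),
        stringsAsFactors = FALSE)
      env <- apply(filt, 2, function(v) Mod(analytic_signal(v)))
      cm <- stats::cor(env)
      p <- pairs$pairs
      ec[[length(ec) + 1L]] <- data.frame(
        trial = k, label = trials$labels[k], band = bn,
        region_a = p$a, region_b = p$b,
        correlation = cm[cbind(match(p$a, regions), match(p$b, regions))],
        stringsAsFactors = FALSE)
    }
  }
  list(band_power = do.call(rbind, bp), envelope_corr = do.call(rbind, ec))
}
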