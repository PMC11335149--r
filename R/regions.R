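#' @useDynLib neurixn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical region / band conventions.  The ten cortical regions of interest
# are the left and right occipital, parietal, temporal, central and frontal
# parcels.  The order below is fixed so that learned spatial filters are
# comparable across runs and participants.
.REGION_ORDER <- c("LO", "LP", "LT", "LC", "LF", "RO", "RP", "RT", "RC", "RF")
.BAND_ORDER <- c("delta_theta", "alpha", "beta")
.LOBE_CODES <- c(occipital = "O", parietal = "P", temporal = "T",
                 central = "C", frontal = "F")

#' Canonical region order
#'
#' The fixed ordering of the ten cortical region codes used throughout the
#' package: left occipital/parietal/temporal/central/frontal, then the right
#' hemisphere in the same lobe order.
#'
#' @return Character vector of length 10.
#' @export
canonical_region_order <- function() .REGION_ORDER

#' Canonical band-enhancement order
#'
#' Order of the three GED enhancement bands within each region's channel
#' block: delta-theta, alpha, beta.
#'
#' @return Character vector of length 3.
#' @export
canonical_band_order <- function() .BAND_ORDER

#' Frequency band specification
#'
#' @param band_code Character name of the band.
#' @param low_hz,high_hz Band edges in Hz, `0 < low_hz < high_hz`.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(band_code, low_hz, high_hz) {
  stopifnot(is.character(band_code), length(band_code) == 1L)
  if (!(is.numeric(low_hz) && is.numeric(high_hz) &&
        low_hz > 0 && high_hz > low_hz)) {
    stop("invalid band: need 0 < low_hz < high_hz", call. = FALSE)
  }
  structure(list(band_code = band_code, low_hz = low_hz, high_hz = high_hz),
            class = "band_spec")
}

#' Canonical GED enhancement bands
#'
#' Delta-theta (2-8 Hz), alpha (8-13 Hz) and beta (15-32 Hz): the three bands
#' for which each region's sources are reduced to one enhanced component.
#'
#' @return Named list of three [band_spec()] objects in canonical order.
#' @export
canonical_bands <- function() {
  list(delta_theta = band_spec("delta_theta", 2, 8),
       alpha = band_spec("alpha", 8, 13),
       beta = band_spec("beta", 15, 32))
}

#' Baseline / ablation frequency bands
#'
#' The four canonical EEG bands used by the band-power baseline and by the
#' band-removal retests: delta (2-4), theta (4-8), alpha (8-13), beta
#' (15-32 Hz).
#'
#' @return Named list of four [band_spec()] objects.
#' @export
baseline_bands <- function() {
  list(delta = band_spec("delta", 2, 4),
       theta = band_spec("theta", 4, 8),
       alpha = band_spec("alpha", 8, 13),
       beta = band_spec("beta", 15, 32))
}

#' Hemisphere of a region code
#' @param region_code Character vector of region codes.
#' @return "left" or "right" per element.
#' @export
region_hemisphere <- function(region_code) {
  ifelse(substr(region_code, 1, 1) == "L", "left", "right")
}

#' Lobe name of a region code
#' @param region_code Character vector of region codes.
#' @return Lobe name ("occipital", "parietal", ...) per element.
#' @export
region_lobe <- function(region_code) {
  names(.LOBE_CODES)[match(substr(region_code, 2, 2), .LOBE_CODES)]
}

#' Enumerate all unordered region pairs
#'
#' Builds the canonical index of the `choose(n, 2)` unordered region pairs in
#' lexicographic order of their positions in `region_order`.  With the ten
#' canonical regions this yields the 45 interaction channels of the decoder.
#'
#' @param region_order Character vector of distinct region codes.
#' @return A `pair_index` object: list with `pairs` (data frame with columns
#'   `index`, `i`, `j`, `a`, `b`), `region_order`, and `n_pairs`.
#' @export
make_pair_index <- function(region_order = canonical_region_order()) {
  if (anyDuplicated(region_order) || length(region_order) < 2L) {
    stop("invalid region order: codes must be distinct (>= 2)", call. = FALSE)
  }
  n <- length(region_order)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ij <- ij[order(ij[, "row"], ij[, "col"]), , drop = FALSE]
  pairs <- data.frame(
    index = seq_len(nrow(ij)),
    i = unname(ij[, "row"]), j = unname(ij[, "col"]),
    a = region_order[ij[, "row"]], b = region_order[ij[, "col"]],
    stringsAsFactors = FALSE)
  structure(list(pairs = pairs, region_order = region_order,
                 n_pairs = nrow(pairs)),
            class = "pair_index")
}

#' Look up the index of an unordered region pair
#'
#' Symmetric in its two arguments: `pair_lookup(p, "RP", "LP")` equals
#' `pair_lookup(p, "LP", "RP")`.
#'
#' @param pair_index A [make_pair_index()] object.
#' @param region_a,region_b Region codes.
#' @return Integer pair index (1-based).
#' @export
pair_lookup <- function(pair_index, region_a, region_b) {
  stopifnot(inherits(pair_index, "pair_index"))
  p <- pair_index$pairs
  hit <- which((p$a == region_a & p$b == region_b) |
               (p$a == region_b & p$b == region_a))
  if (length(hit) != 1L) {
    stop("unknown region pair: ", region_a, "-", region_b, call. = FALSE)
  }
  p$index[hit]
}

#' Channel index of the 30-channel enhanced representation
#'
#' Region-major, band-minor: each region contributes three consecutive
#' channels (delta-theta, alpha, beta).
#'
#' @param region_order Region codes; defaults to the canonical order.
#' @param band_order Band codes; defaults to the canonical order.
#' @return Data frame with columns `channel`, `region`, `band`.
#' @export
channel_index <- function(region_order = canonical_region_order(),
                          band_order = canonical_band_order()) {
  data.frame(
    channel = seq_len(length(region_order) * length(band_order)),
    region = rep(region_order, each = length(band_order)),
    band = rep(band_order, times = length(region_order)),
    stringsAsFactors = FALSE)
}
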