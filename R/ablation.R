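# Ablation retests of trained decoders (no retraining).  Kernel masks zero
# selected interaction columns of the spatial filters; input-side band
# filters remove or isolate a frequency band in the test windows.  Because
# the only path from the input to the classifier runs through the 45
# interaction channels, zeroing every column that touches a region makes the
# logits exactly invariant to that region's input channels.

new_ablation_mask <- function(kind, zeroed = integer(0), band = NULL,
                              label = kind) {
  kernel_kinds <- c("region", "hemisphere", "cluster")
  input_kinds <- c("band_stop", "band_pass")
  stopifnot(kind %in% c(kernel_kinds, input_kinds))
  if (kind %in% kernel_kinds && !is.null(band)) {
    stop("kernel-kind masks specify pair indices only", call. = FALSE)
  }
  if (kind %in% input_kinds && length(zeroed)) {
    stop("input-kind masks specify a band only", call. = FALSE)
  }
  structure(list(kind = kind, zeroed_pair_indices = as.integer(zeroed),
                 band = band, label = label),
            class = "ablation_mask")
}

#' Kernel mask removing one lobe from both hemispheres
#'
#' Zeroes every interaction column whose pair contains the left or right
#' instance of the lobe (17 of the 45 columns: 9 + 9 minus the shared
#' left-right pair).
#'
#' @param region_name One of "occipital", "parietal", "temporal", "central",
#'   "frontal".
#' @param pair_index A [make_pair_index()] object.
#' @return An `ablation_mask` of kind "region".
#' @export
region_mask <- function(region_name, pair_index = make_pair_index()) {
  if (!region_name %in% names(.LOBE_CODES)) {
    stop("unknown region name: ", region_name, call. = FALSE)
  }
  codes <- pair_index$region_order[region_lobe(pair_index$region_order) ==
                                     region_name]
  p <- pair_index$pairs
  idx <- p$index[p$a %in% codes | p$b %in% codes]
  new_ablation_mask("region", idx, label = paste0("region:", region_name))
}

#' Kernel mask removing one hemisphere
#'
#' Zeroes every interaction column whose pair contains any region of the
#' given hemisphere (35 of 45: all but the 10 pairs internal to the other
#' hemisphere).
#'
#' @param side "left" or "right".
#' @param pair_index A [make_pair_index()] object.
#' @return An `ablation_mask` of kind "hemisphere".
#' @export
hemisphere_mask <- function(side = c("left", "right"),
                            pair_index = make_pair_index()) {
  side <- match.arg(side)
  codes <- pair_index$region_order[region_hemisphere(pair_index$region_order)
                                   == side]
  p <- pair_index$pairs
  idx <- p$index[p$a %in% codes | p$b %in% codes]
  new_ablation_mask("hemisphere", idx, label = paste0("hemisphere:", side))
}

#' Kernel mask from the significant interactions of a cluster centroid
#'
#' @param centroid Numeric 45-vector (a group-level cluster centroid).
#' @param p_threshold Threshold passed to [significant_interactions()].
#' @param label Mask label.
#' @return An `ablation_mask` of kind "cluster".
#' @export
cluster_mask <- function(centroid, p_threshold = 0.05, label = "cluster") {
  si <- significant_interactions(centroid, p_threshold)
  new_ablation_mask("cluster", si$indices, label = label)
}

#' Apply a kernel mask to a decoder
#'
#' Returns a copy of the model whose spatial-filter columns at the masked
#' pair indices are zero in all temporal maps; the original model is
#' untouched.
#'
#' @param model A `neurixn_decoder`.
#' @param mask A kernel-kind `ablation_mask`.
#' @return The ablated decoder copy.
#' @export
apply_kernel_mask <- function(model, mask) {
  stopifnot(inherits(mask, "ablation_mask"))
  if (!mask$kind %in% c("region", "hemisphere", "cluster")) {
    stop("wrong mask kind: input-side masks are applied with ",
         "band_filter_inputs()", call. = FALSE)
  }
  model$params$w4[, mask$zeroed_pair_indices] <- 0
  model
}

#' Band-filter the windows of a window set
#'
#' Zero-phase order-4 Butterworth band-stop (`mode = "stop"`) or band-pass
#' (`mode = "pass"`) applied per channel; shapes are preserved.  Band-pass
#' mode additionally applies a 0.5 Hz high-pass DC block.
#'
#' @param windows A `window_set`.
#' @param band A [band_spec()] inside the Nyquist range.
#' @param mode "stop" or "pass".
#' @return A filtered `window_set`.
#' @export
band_filter_inputs <- function(windows, band, mode = c("stop", "pass")) {
  mode <- match.arg(mode)
  fs <- windows$fs
  if (!(band$low_hz > 0 && band$high_hz > band$low_hz &&
        band$high_hz <= fs / 2)) {
    stop("invalid band for fs ", fs, call. = FALSE)
  }
  bf <- if (band$high_hz >= (fs / 2) * (1 - 1e-9)) {
    # band extends to Nyquist: stop -> low-pass, pass -> high-pass
    signal::butter(4, band$low_hz / (fs / 2),
                   type = if (mode == "stop") "low" else "high")
  } else {
    signal::butter(4, c(band$low_hz, band$high_hz) / (fs / 2), type = mode)
  }
  dc <- if (mode == "pass") {
    signal::butter(2, 0.5 / (fs / 2), type = "high")
  } else NULL
  d <- windows$data
  for (k in seq_len(dim(d)[3])) {
    v <- nx_filtfilt_mat(bf$b, bf$a, d[, , k])
    if (!is.null(dc)) v <- nx_filtfilt_mat(dc$b, dc$a, v)
    d[, , k] <- v
  }
  out <- windows
  out$data <- d
  out
}

#' Ablation report for a trained decoder
#'
#' Re-evaluates a trained model on the test windows under each kernel mask
#' and/or input band filter, against the unablated model.
#'
#' @param model A trained `neurixn_decoder`.
#' @param test_windows A `window_set`.
#' @param masks List of kernel-kind `ablation_mask`s (possibly empty).
#' @param bands Named list of [band_spec()]s for input-side ablation
#'   (possibly empty).
#' @param band_mode "stop" (remove the band from the inputs) or "pass"
#'   (keep only the band).
#' @return Data frame with columns `condition`, `accuracy`,
#'   `delta_accuracy` (condition minus original; 0 for the original row).
#' @export
ablation_report <- function(model, test_windows, masks = list(),
                            bands = list(), band_mode = "stop") {
  acc0 <- evaluate_accuracy(model, test_windows)
  rows <- data.frame(condition = "original", accuracy = acc0,
                     delta_accuracy = 0, stringsAsFactors = FALSE)
  for (mask in masks) {
    acc <- evaluate_accuracy(apply_kernel_mask(model, mask), test_windows)
    rows <- rbind(rows, data.frame(condition = mask$label, accuracy = acc,
                                   delta_accuracy = acc - acc0))
  }
  for (bn in names(bands)) {
    fw <- band_filter_inputs(test_windows, bands[[bn]], band_mode)
    acc <- evaluate_accuracy(model, fw)
    rows <- rbind(rows,
                  data.frame(condition = paste0("band_", band_mode, ":", bn),
                             accuracy = acc, delta_accuracy = acc - acc0))
  }
  rows
}
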