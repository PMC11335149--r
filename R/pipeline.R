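# End-to-end orchestration: GED enhancement fitted on the training blocks of
# a fold, window construction, decoder training, and the parameter-recovery
# replicate used to validate the whole pipeline on synthetic data.

#' Enhance and window one participant for one within-participant fold
#'
#' Fits GED components on the fold's training trials only, enhances all
#' trials with those components, and cuts sliding windows that carry the
#' fold's block assignment.
#'
#' @param rts A [region_trial_set()].
#' @param split A within-scope `cv_split` from [make_within_splits()].
#' @param window_seconds,overlap_fraction Windowing parameters (study
#'   defaults: 5 s, 50%).
#' @param bands GED bands; default [canonical_bands()].
#' @param shrinkage GED reference-covariance shrinkage.
#' @return List with `windows` (a `window_set`), `components`, `enhanced`.
#' @export
prepare_fold_windows <- function(rts, split, window_seconds = 5,
                                 overlap_fraction = 0.5,
                                 bands = canonical_bands(),
                                 shrinkage = 0.01) {
  comps <- fit_gedb_components(rts, split$train_ids, bands, shrinkage)
  enh <- enhance_participant(rts, comps, bands)
  ws <- bind_windows(lapply(seq_along(enh), function(k) {
    sliding_windows(enh[[k]], window_seconds, overlap_fraction,
                    block_id = split$block_of[k],
                    participant_id = rts$participant_id)
  }))
  list(windows = ws, components = comps, enhanced = enh)
}

#' Train one within-participant fold end to end
#'
#' @param rts A [region_trial_set()].
#' @param fold Fold number (1-4).
#' @param window_seconds,overlap_fraction Windowing parameters.
#' @param epochs,batch_size,lr Training parameters.
#' @param seed Seed for the block assignment, model initialization and
#'   training.
#' @param shuffle_labels If `TRUE`, window labels are globally permuted
#'   (seeded) before training - the null control.
#' @return The `train_report`, with `windows` and `split` attached.
#' @export
run_within_fold <- function(rts, fold = 1, window_seconds = 5,
                            overlap_fraction = 0.5, epochs = 200,
                            batch_size = 32, lr = 1e-3, seed = 1,
                            shuffle_labels = FALSE) {
  splits <- make_within_splits(rts, 4, seed = seed)
  split <- splits[[fold]]
  prep <- prepare_fold_windows(rts, split, window_seconds, overlap_fraction)
  ws <- prep$windows
  if (shuffle_labels) {
    set.seed(seed + 1L)
    ws$meta$label <- sample(ws$meta$label)
  }
  cfg <- decoder_config(input_samples = dim(ws$data)[2], fs = ws$fs)
  model <- build_decoder(cfg, seed = seed)
  rep <- train_decoder(model, split, ws, epochs = epochs,
                       batch_size = batch_size, lr = lr, seed = seed,
                       participant_id = rts$participant_id)
  rep$windows <- ws
  rep$split <- split
  rep$components <- prep$components
  rep
}

#' One parameter-recovery replicate on synthetic data
#'
#' Trains one within-participant fold on a synthetic participant with a
#' planted band-specific pair coupling, then asks: (1) what is the test
#' accuracy; (2) do the significant interactions of any cluster centroid of
#' the learned spatial filters contain the planted pair; (3) which
#' band-stop input ablation causes the largest accuracy drop.
#'
#' @param rts A synthetic [region_trial_set()].
#' @param planted A planted-pair entry from the generator spec.
#' @param epochs,seed,... Passed to [run_within_fold()].
#' @return List with `accuracy`, `recovered` (logical), `band_drops`
#'   (named accuracy drops), `top_band`, `report`.
#' @export
recovery_replicate <- function(rts, planted, epochs = 80, seed = 1, ...) {
  rep <- run_within_fold(rts, fold = 1, epochs = epochs, seed = seed, ...)
  filt <- align_filter_signs(extract_spatial_filters(rep$model)$filters)
  km <- kmeans_cosine(filt, k = min(4, nrow(filt)), seed = seed)
  # both clustering levels: individual k-means centroids and the flat
  # group-level centroids of their agglomeration
  grp <- hierarchical_group_clusters(km$centroids,
                                     min(3, nrow(km$centroids)))
  centroids <- rbind(km$centroids, grp$centroids)
  target <- pair_lookup(rep$model$pair_index, planted$region_i,
                        planted$region_j)
  recovered <- any(vapply(seq_len(nrow(centroids)), function(c_) {
    target %in% significant_interactions(centroids[c_, ])$indices
  }, logical(1)))
  test_w <- subset_windows(rep$windows, trial_ids = rep$split$test_ids)
  ab <- ablation_report(rep$model, test_w, bands = baseline_bands(),
                        band_mode = "stop")
  band_rows <- grepl("^band_stop:", ab$condition)
  drops <- -ab$delta_accuracy[band_rows]
  names(drops) <- sub("^band_stop:", "", ab$condition[band_rows])
  list(accuracy = rep$test_accuracy, recovered = recovered,
       band_drops = drops, top_band = names(drops)[which.max(drops)],
       report = rep)
}

#' Seeded parameter-recovery study on synthetic data
#'
#' Generates the synthetic dataset of `spec` (default: 4 participants with
#' 24 trials each), then runs `n_replicates` seeded [recovery_replicate()]s,
#' cycling over the participants, each with its own training seed.
#'
#' @param spec A [generator_spec()].
#' @param n_replicates Number of replicates.
#' @param epochs Training epochs per replicate.
#' @param base_seed Integer; replicate r uses seed `base_seed + r`.
#' @return Data frame with one row per replicate: `replicate`,
#'   `participant_id`, `seed`, `accuracy`, `recovered`, `top_band`, and the
#'   four band-stop accuracy drops.
#' @export
run_recovery_study <- function(spec = generator_spec(), n_replicates = 10,
                               epochs = 80, base_seed = 100) {
  ds <- generate_attention_dataset(spec)
  planted <- spec$planted_pairs[[1]]
  rows <- lapply(seq_len(n_replicates), function(r) {
    rts <- ds$participants[[(r - 1) %% length(ds$participants) + 1]]
    rr <- recovery_replicate(rts, planted, epochs = epochs,
                             seed = base_seed + r)
    data.frame(replicate = r, participant_id = rts$participant_id,
               seed = base_seed + r, accuracy = rr$accuracy,
               recovered = rr$recovered, top_band = rr$top_band,
               drop_delta = rr$band_drops[["delta"]],
               drop_theta = rr$band_drops[["theta"]],
               drop_alpha = rr$band_drops[["alpha"]],
               drop_beta = rr$band_drops[["beta"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
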