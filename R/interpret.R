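# Interpretation of trained decoders.  The learned 45-dimensional spatial
# filters are clustered in two levels - cosine k-means per participant (k =
# 4, the number of filters per model) and agglomerative average-linkage
# clustering of the per-participant centroids at the group level - and each
# filter/centroid is thresholded into its significant interaction entries by
# z-scoring within the filter.  Because a filter and its negation implement
# the same decoder up to downstream sign absorption, rows are sign-aligned
# before any cosine computation.

#' Sign-align filter rows
#'
#' Multiplies each row by +/-1 so that its largest-magnitude entry is
#' positive; a row and its negation map to the same output.
#'
#' @param filters Numeric matrix (n x 45), no all-zero rows.
#' @return Matrix of the same shape.
#' @export
align_filter_signs <- function(filters) {
  if (is.null(dim(filters))) filters <- matrix(filters, 1)
  t(apply(filters, 1, fix_sign))
}

unit_rows <- function(x) {
  n <- sqrt(rowSums(x^2))
  if (any(n == 0)) stop("degenerate (all-zero) filter row", call. = FALSE)
  x / n
}

cosine_dist <- function(x) {
  u <- unit_rows(x)
  d <- 1 - tcrossprod(u)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' k-means clustering under cosine distance
#'
#' Spherical k-means: points and centroids are unit-normalized, assignment
#' maximizes cosine similarity, and centroids are the normalized means of
#' their members.  The algorithm restarts `restarts` times from random
#' centroid draws and keeps the solution with the smallest within-cluster
#' sum of cosine distances.
#'
#' @param filters Numeric matrix (n x d), `n >= k`.
#' @param k Number of clusters (4 in the study design: one per spatial
#'   filter).
#' @param restarts Random restarts.
#' @param max_iter Iteration cap per restart.
#' @param seed Integer seed.
#' @return A `cluster_result`: list with `level = "individual"`, `k`,
#'   `centroids` (k x d), `assignments`, `inertia` (within-cluster cosine
#'   distance sum), `silhouette` (mean silhouette width under cosine
#'   distance, `NA` when undefined).
#' @export
kmeans_cosine <- function(filters, k = 4, restarts = 10, max_iter = 100,
                          seed = 1) {
  n <- nrow(filters)
  if (n < k) stop("infeasible: fewer filters than clusters", call. = FALSE)
  u <- unit_rows(filters)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    cen <- u[sample.int(n, k), , drop = FALSE]
    assign_old <- rep(0L, n)
    for (it in seq_len(max_iter)) {
      sims <- tcrossprod(u, cen)
      assign <- max.col(sims, ties.method = "first")
      for (c_ in seq_len(k)) {
        members <- which(assign == c_)
        if (!length(members)) {
          # re-seed an empty cluster with the worst-fitting point
          worst <- which.min(sims[cbind(seq_len(n), assign)])
          assign[worst] <- c_
          members <- worst
        }
        m <- colMeans(u[members, , drop = FALSE])
        nv <- sqrt(sum(m^2))
        cen[c_, ] <- if (nv > 0) m / nv else u[members[1], ]
      }
      if (identical(assign, assign_old)) break
      assign_old <- assign
    }
    sims <- tcrossprod(u, cen)
    assign <- max.col(sims, ties.method = "first")
    inertia <- sum(1 - sims[cbind(seq_len(n), assign)])
    if (is.null(best) || inertia < best$inertia) {
      best <- list(centroids = cen, assignments = assign, inertia = inertia)
    }
  }
  structure(list(level = "individual", k = k, centroids = best$centroids,
                 assignments = best$assignments, inertia = best$inertia,
                 silhouette = mean_silhouette(best$assignments,
                                              cosine_dist(filters))),
            class = "cluster_result")
}

mean_silhouette <- function(assignments, dmat) {
  if (length(unique(assignments)) < 2 ||
      length(assignments) <= length(unique(assignments))) {
    return(NA_real_)
  }
  s <- cluster::silhouette(assignments, dmatrix = dmat)
  mean(s[, "sil_width"])
}

#' Group-level hierarchical clustering of filter centroids
#'
#' Agglomerative clustering with average linkage on cosine distances,
#' cut at the requested number of flat clusters (the study uses 3 for the
#' within-participant and 4 for the cross-participant analysis).
#'
#' @param centroids Numeric matrix (n x d) of per-participant centroids
#'   (sign-aligned).
#' @param n_clusters Number of flat clusters, `<= n`.
#' @return A `cluster_result` with `level = "group"`, the normalized mean
#'   centroid per cluster, assignments, the `hclust` merge heights, and the
#'   mean silhouette width.
#' @export
hierarchical_group_clusters <- function(centroids, n_clusters) {
  n <- nrow(centroids)
  if (n < n_clusters) {
    stop("infeasible: fewer centroid vectors than clusters", call. = FALSE)
  }
  d <- cosine_dist(centroids)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  assign <- stats::cutree(hc, k = n_clusters)
  u <- unit_rows(centroids)
  cen <- t(vapply(seq_len(n_clusters), function(c_) {
    m <- colMeans(u[assign == c_, , drop = FALSE])
    m / sqrt(sum(m^2))
  }, numeric(ncol(centroids))))
  structure(list(level = "group", k = n_clusters, centroids = cen,
                 assignments = assign, heights = hc$height, hclust = hc,
                 silhouette = mean_silhouette(assign, d)),
            class = "cluster_result")
}

#' Significant interactions of a spatial filter
#'
#' Z-transforms the 45 filter entries relative to the filter's own mean and
#' standard deviation (population SD, the array-zscore convention),
#' converts each z-value to a two-sided normal p-value, and retains the
#' entries with `p < p_threshold`.
#'
#' @param filter Numeric vector (length 45), non-constant.
#' @param p_threshold Uncorrected significance threshold (default 0.05).
#' @return List with `indices` (1-based positions retained), `z_values`,
#'   `p_values`, `p_threshold`.
#' @export
significant_interactions <- function(filter, p_threshold = 0.05) {
  mu <- mean(filter)
  s <- sqrt(mean((filter - mu)^2))
  if (!is.finite(s) || s == 0) {
    stop("degenerate filter: zero standard deviation", call. = FALSE)
  }
  z <- (filter - mu) / s
  p <- 2 * stats::pnorm(-abs(z))
  list(indices = which(p < p_threshold), z_values = z, p_values = p,
       p_threshold = p_threshold)
}

#' Inertia / silhouette scan over cluster counts
#'
#' Runs [kmeans_cosine()] for each k and tabulates the within-cluster cosine
#' inertia and the mean silhouette width, the basis of elbow/silhouette
#' selection of the cluster count.
#'
#' @param filters Numeric matrix (n x d).
#' @param k_range Integer vector of cluster counts within `[2, n - 1]`.
#' @param ... Passed to [kmeans_cosine()].
#' @return Data frame with columns `k`, `inertia`, `silhouette`.
#' @export
elbow_silhouette_scan <- function(filters, k_range, ...) {
  stopifnot(all(k_range >= 2), all(k_range <= nrow(filters) - 1))
  rows <- lapply(k_range, function(k) {
    cr <- kmeans_cosine(filters, k = k, ...)
    data.frame(k = k, inertia = cr$inertia, silhouette = cr$silhouette)
  })
  do.call(rbind, rows)
}
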