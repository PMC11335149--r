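# Paired nonparametric statistics and result aggregation.

#' Wilcoxon signed-rank test
#'
#' W is the sum of the ranks of the positive differences `a - b` (zero
#' differences dropped; tied absolute differences get average ranks).  The
#' two-sided p-value is exact for n <= 25: from the signed-rank
#' distribution when the absolute differences are untied, and by direct
#' enumeration of all 2^n sign patterns when they are tied (feasible up to
#' n = 15; ties with larger n, like n > 25, fall back to the normal
#' approximation with continuity and tie correction).
#'
#' @param a,b Paired numeric vectors of equal length >= 5.
#' @return List with `W`, `p_value`, `n` (non-zero pairs), `method`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 5)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    stop("degenerate comparison: all paired differences are zero",
         call. = FALSE)
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    # psignrank gives P(W+ <= q) under the null
    p <- 2 * min(stats::psignrank(W, n),
                 stats::psignrank(W - 1, n, lower.tail = FALSE))
    p <- min(1, p)
    method <- "exact"
  } else if (n <= 15) {
    # ties: enumerate the 2^n equiprobable sign patterns directly
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    W_all <- as.vector(signs %*% r)
    tol <- 1e-9
    p <- min(1, 2 * min(mean(W_all <= W + tol), mean(W_all >= W - tol)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_counts <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_counts^3 - tie_counts) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  list(W = W, p_value = p, n = n, method = method)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values; monotone and bounded by 1.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
fdr_correct <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Aggregate per-fold accuracy reports
#'
#' Fold accuracies are averaged within each participant, and the median of
#' the per-participant means summarizes the group, matching the reporting
#' convention of per-participant points with a group median.
#'
#' @param reports List of `train_report`s (or any lists with
#'   `test_accuracy` and `participant_id`).
#' @return List with `per_participant` (data frame: `participant_id`,
#'   `n_folds`, `mean_accuracy`) and `median_accuracy`.
#' @export
aggregate_results <- function(reports) {
  stopifnot(length(reports) >= 1)
  df <- data.frame(
    participant_id = vapply(reports, function(r) as.character(r$participant_id),
                            character(1)),
    accuracy = vapply(reports, function(r) r$test_accuracy, numeric(1)),
    stringsAsFactors = FALSE)
  agg <- stats::aggregate(accuracy ~ participant_id, df, mean)
  cnt <- stats::aggregate(accuracy ~ participant_id, df, length)
  per <- data.frame(participant_id = agg$participant_id,
                    n_folds = cnt$accuracy,
                    mean_accuracy = agg$accuracy,
                    stringsAsFactors = FALSE)
  per <- per[order(per$participant_id), , drop = FALSE]
  rownames(per) <- NULL
  list(per_participant = per,
       median_accuracy = stats::median(per$mean_accuracy))
}
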