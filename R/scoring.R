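#' Per-channel anomaly scores
#'
#' The score of channel i is the squared distance between its rows in the two
#' normalized views, `s_i = ||Z_st'[i, ] - Z_se'[i, ]||^2` — the per-node
#' contribution to the invariance loss. A channel whose semantic (own-feature)
#' embedding agrees with its structural (neighbor-aggregated) embedding scores
#' near zero; weak structural-semantic correlation gives a large score.
#' `sum(node_scores) == invariance_loss` by construction.
#'
#' @param Zp_st,Zp_se Normalized embeddings of one clip
#'   ([normalize_embeddings]).
#' @return Nonnegative length-N vector.
#' @export
node_scores <- function(Zp_st, Zp_se) {
  if (!all(dim(Zp_st) == dim(Zp_se))) stop("shape mismatch", call. = FALSE)
  rowSums((Zp_st - Zp_se)^2)
}

#' Aggregate node scores into a clip score
#' @param scores Nonnegative node-score vector.
#' @param aggregation `"mean"` (default) or `"max"`.
#' @return Scalar clip score.
#' @export
clip_score <- function(scores, aggregation = c("mean", "max")) {
  aggregation <- match.arg(aggregation)
  if (length(scores) == 0) stop("empty score vector", call. = FALSE)
  if (aggregation == "mean") mean(scores) else max(scores)
}

#' Score a clip with a trained model
#'
#' Encodes the clip's graph and its identity counterpart with the shared
#' weights, takes posterior means (no sampling, so scores are deterministic),
#' normalizes both views, and returns per-channel and aggregate scores.
#'
#' @param graph An `eeg_graph`.
#' @param params Trained `gca_params`.
#' @param aggregation Clip-level aggregation rule.
#' @return List `node_scores`, `clip_score`, `aggregation`.
#' @export
score_clip <- function(graph, params, aggregation = "mean") {
  if (params$dims$D != ncol(graph$X)) {
    stop(sprintf("feature dimension mismatch: model D = %d, clip D = %d",
                 params$dims$D, ncol(graph$X)), call. = FALSE)
  }
  post_st <- encode(graph, params)
  g_id <- eeg_graph(build_identity_graph(nrow(graph$X)), graph$X, graph$labels)
  post_se <- encode(g_id, params)
  s <- node_scores(normalize_embeddings(post_st$mu), normalize_embeddings(post_se$mu))
  list(node_scores = s, clip_score = clip_score(s, aggregation),
       aggregation = aggregation)
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic with ties
#' averaged; invariant to any strictly monotone transform of the scores.
#' @param scores Numeric vector (higher = more anomalous).
#' @param labels Binary vector (1 = anomalous); both classes must be present.
#' @return Scalar in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- check_labels(scores, labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision
#'
#' Area under the precision-recall curve by step interpolation: the sum over
#' positives, in decreasing score order, of precision at that rank times the
#' recall increment. Ties are broken deterministically by original index.
#' @inheritParams auc_score
#' @return Scalar in \[0, 1\].
#' @export
average_precision <- function(scores, labels) {
  labels <- check_labels(scores, labels)
  ord <- order(-scores, seq_along(scores))
  y <- labels[ord]
  prec <- cumsum(y) / seq_along(y)
  sum(prec[y == 1]) / sum(y)
}

check_labels <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) stop("scores / labels length mismatch", call. = FALSE)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary", call. = FALSE)
  if (length(unique(labels)) < 2) stop("both classes must be present", call. = FALSE)
  labels
}

#' Specificity at a score threshold
#'
#' True-negative rate when calling "anomalous" for `score > threshold`.
#' @inheritParams auc_score
#' @param threshold Score cutoff.
#' @return List: `specificity` = TN / (TN + FP), `threshold`, and the
#'   confusion `counts` (TP, FP, TN, FN).
#' @export
specificity_at_threshold <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary", call. = FALSE)
  if (!any(labels == 0)) stop("no negative samples", call. = FALSE)
  pred <- as.integer(scores > threshold)
  counts <- c(TP = sum(pred == 1 & labels == 1), FP = sum(pred == 1 & labels == 0),
              TN = sum(pred == 0 & labels == 0), FN = sum(pred == 0 & labels == 1))
  list(specificity = unname(counts["TN"] / (counts["TN"] + counts["FP"])),
       threshold = threshold, counts = as.list(counts))
}

#' Choose an operating threshold from normal scores
#'
#' The q-th empirical quantile (linear interpolation) of anomaly scores on
#' held-out normal data; the default q = 0.95 targets a ~95% specificity
#' operating point.
#' @param normal_scores Scores of known-normal items.
#' @param q Quantile in (0, 1\].
#' @return Scalar threshold.
#' @export
choose_threshold <- function(normal_scores, q = 0.95) {
  if (length(normal_scores) == 0) stop("empty score sample", call. = FALSE)
  stopifnot(q > 0, q <= 1)
  unname(stats::quantile(normal_scores, q, type = 7))
}

#' Evaluation report
#'
#' AUC, average precision and specificity (at the given or 95th-percentile-
#' of-negatives threshold) for one score/label set.
#' @inheritParams auc_score
#' @param threshold Optional; default is the 0.95 quantile of the negative
#'   class's scores.
#' @return `gca_eval` list: `auc`, `ap`, `specificity`, `threshold`, `counts`.
#' @export
evaluate_scores <- function(scores, labels, threshold = NULL) {
  labels <- check_labels(scores, labels)
  threshold <- threshold %||% choose_threshold(scores[labels == 0], 0.95)
  spc <- specificity_at_threshold(scores, labels, threshold)
  structure(list(auc = auc_score(scores, labels),
                 ap = average_precision(scores, labels),
                 specificity = spc$specificity, threshold = threshold,
                 counts = spc$counts), class = "gca_eval")
}

#' @export
print.gca_eval <- function(x, ...) {
  cat(sprintf("AUC %.4f | AP %.4f | specificity %.4f (threshold %.4g)\n",
              x$auc, x$ap, x$specificity, x$threshold))
  invisible(x)
}
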