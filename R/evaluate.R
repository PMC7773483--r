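#' Average precision (AUCPR estimate)
#'
#' Area under the precision-recall curve estimated as
#' \eqn{\sum_k (R_k - R_{k-1}) P_k} over descending score thresholds, which
#' avoids the optimism of trapezoidal PR interpolation. Tied scores enter
#' as a single threshold block. Sparse-graph edge prediction is a
#' needle-in-a-haystack task, so this prevalence-sensitive area is the
#' headline simulation metric.
#'
#' @param scores Numeric vector of prediction scores.
#' @param labels Binary vector (0/1 or logical) of the same length, with at
#'   least one positive.
#' @return Average precision in [0, 1].
#' @examples
#' average_precision(c(0.9, 0.8, 0.7), c(1, 0, 1))  # 5/6
#' @export
average_precision <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels)
  if (n_pos == 0) stop("average_precision needs at least one positive label")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  block_end <- cumsum(rle(s)$lengths)   # last index of each tie block
  tp <- cumsum(l)[block_end]
  prec <- tp / block_end
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' AUCPR of a predicted edge matrix against a true graph
#'
#' Flattens score and truth matrices (parent rows, child columns) and
#' delegates to \code{\link{average_precision}}. The diagonal (lagged
#' self-edges) is part of the task by default.
#'
#' @param scores |V| x |V| numeric matrix of edge confidences.
#' @param truth |V| x |V| binary matrix.
#' @param include_diagonal Keep self-edges in the evaluation (default
#'   \code{TRUE}).
#' @return Average precision in [0, 1].
#' @export
aucpr_of_prediction <- function(scores, truth, include_diagonal = TRUE) {
  scores <- as.matrix(scores)
  truth <- as.matrix(truth)
  stopifnot(all(dim(scores) == dim(truth)))
  keep <- if (include_diagonal) rep(TRUE, length(scores))
          else as.vector(row(scores) != col(scores))
  average_precision(as.vector(scores)[keep], as.vector(truth)[keep])
}

#' Paired t-statistic of method scores against a baseline
#'
#' \code{t = mean(d) / (sd(d) / sqrt(K))} on the paired differences
#' \code{d = method - baseline} (sd with K - 1 denominator). When the
#' differences have zero variance the statistic is \code{+/-Inf} with the
#' sign of the mean (0 for identically zero differences).
#'
#' @param method_scores,baseline_scores Equal-length numeric vectors
#'   (K >= 2), paired by instance.
#' @return The paired t-statistic.
#' @export
paired_t_statistic <- function(method_scores, baseline_scores) {
  stopifnot(length(method_scores) == length(baseline_scores),
            length(method_scores) >= 2L)
  d <- method_scores - baseline_scores
  s <- stats::sd(d)
  m <- mean(d)
  if (s == 0) return(if (m == 0) 0 else sign(m) * Inf)
  m / (s / sqrt(length(d)))
}

prob_graph <- function(edge_probs, threshold) {
  adj <- (as.matrix(edge_probs) >= threshold) * 1L
  igraph::graph_from_adjacency_matrix(adj, mode = "directed")
}

#' Descendant set of a vertex at an edge-probability threshold
#'
#' Vertices reachable from \code{source} via directed edges whose
#' probability is at least \code{threshold}; the source itself is excluded.
#'
#' @param edge_probs |V| x |V| matrix of edge probabilities (parent rows).
#' @param source Source vertex: index or name.
#' @param threshold Probability cutoff in [0, 1].
#' @return Integer vector of descendant vertex indices.
#' @export
descendant_set <- function(edge_probs, source, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  edge_probs <- as.matrix(edge_probs)
  V <- ncol(edge_probs)
  if (is.character(source)) {
    source <- match(source, colnames(edge_probs))
    if (is.na(source)) stop("unknown source vertex")
  }
  if (source < 1 || source > V) stop("unknown source vertex")
  g <- prob_graph(edge_probs, threshold)
  reach <- as.integer(igraph::subcomponent(g, source, mode = "out"))
  sort(setdiff(reach, source))
}

#' Descendant-set AUCROC
#'
#' Sweeps a threshold over the unique predicted edge probabilities (plus
#' sentinels 0 and above the maximum); at each threshold the predicted
#' descendant set of \code{source} is compared with the gold descendant set
#' to give a (FPR, TPR) point, and the area under the resulting ROC curve
#' is computed by the trapezoidal rule. This is the score used when gold
#' descendants come from interventional data (e.g. phosphosites responding
#' to mTOR inhibition): descendant sets are large, so ROC area is
#' appropriate where edge-level PR area is not.
#'
#' @param edge_probs |V| x |V| matrix of edge probabilities.
#' @param source Source vertex: index or name.
#' @param gold_descendants Gold descendant vertices (indices or names),
#'   non-empty and a proper subset of the non-source vertices.
#' @return AUCROC in [0, 1].
#' @export
descendant_auroc <- function(edge_probs, source, gold_descendants) {
  edge_probs <- as.matrix(edge_probs)
  V <- ncol(edge_probs)
  if (is.character(source)) source <- match(source, colnames(edge_probs))
  if (is.na(source) || source < 1 || source > V) stop("unknown source vertex")
  if (is.character(gold_descendants))
    gold_descendants <- match(gold_descendants, colnames(edge_probs))
  gold <- sort(unique(as.integer(gold_descendants)))
  others <- setdiff(seq_len(V), source)
  if (length(gold) == 0L || !all(gold %in% others) ||
      length(gold) == length(others))
    stop("gold descendant set must be a non-empty proper subset of the non-source vertices")
  negs <- setdiff(others, gold)

  thresholds <- sort(unique(c(0, as.vector(edge_probs),
                              max(edge_probs) + 1e-9)))
  thresholds <- pmin(pmax(thresholds, 0), 1 + 1e-9)
  pts <- t(vapply(thresholds, function(th) {
    d <- descendant_set(edge_probs, source, min(th, 1))
    if (th > 1) d <- integer(0)  # sentinel above max: empty prediction
    c(fpr = length(intersect(d, negs)) / length(negs),
      tpr = length(intersect(d, gold)) / length(gold))
  }, numeric(2L)))
  pts <- pts[order(pts[, "fpr"], pts[, "tpr"]), , drop = FALSE]
  x <- pts[, "fpr"]; y <- pts[, "tpr"]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Dominance comparison of stochastic scores against a deterministic one
#'
#' A stochastic method (scored over K repeat runs) dominates a
#' deterministic method when its minimum score exceeds the other's score;
#' it is dominated when the other's score exceeds its maximum; otherwise
#' neither. Deliberately strict: the ranges must not overlap.
#'
#' @param ssps_scores Numeric vector of K >= 1 repeat-run scores.
#' @param other_score Single score of the deterministic method.
#' @return One of \code{"dominates"}, \code{"dominated"}, \code{"neither"}.
#' @export
dominance <- function(ssps_scores, other_score) {
  stopifnot(length(ssps_scores) >= 1L, length(other_score) == 1L)
  if (min(ssps_scores) > other_score) "dominates"
  else if (other_score > max(ssps_scores)) "dominated"
  else "neither"
}
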