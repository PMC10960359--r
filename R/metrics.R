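# Threshold-free classifier metrics. AUROC uses the Mann-Whitney rank
# identity (midranks handle ties); AUPRC is step-wise average precision
# over distinct thresholds, the tie-safe estimator.

#' Area under the ROC curve
#'
#' Computed via the rank (Mann-Whitney) identity; ties contribute 1/2.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (logical, 0/1, or factor with the positive
#'   class last).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  lab <- as_binary_labels(labels)
  n1 <- sum(lab == 1L); n0 <- sum(lab == 0L)
  if (n1 == 0L || n0 == 0L) stop_data("both classes must be present")
  r <- rank(scores)
  (sum(r[lab == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: `sum((R_k - R_{k-1}) * P_k)` over distinct
#' score thresholds in descending order.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  pr <- pr_points(scores, labels)
  r <- c(0, pr$recall)
  sum(diff(r) * pr$precision)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(as.numeric(labels)))
  if (anyNA(labels)) stop_data("labels must be binary")
  labels
}

#' ROC curve points
#'
#' One point per distinct score threshold (rule: predict positive when
#' score >= threshold), plus the (0,0) and (1,1) endpoints.
#'
#' @inheritParams auroc
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  lab <- as_binary_labels(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; lab <- lab[ord]
  last <- !duplicated(s, fromLast = TRUE) # last index of each tie block
  tp <- cumsum(lab)[last]
  fp <- cumsum(1L - lab)[last]
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fp / sum(lab == 0L)),
             tpr = c(0, tp / sum(lab == 1L)))
}

#' Precision-recall curve points
#'
#' @inheritParams auroc
#' @return Data frame with columns `threshold`, `recall`, `precision`,
#'   one row per distinct threshold in descending order.
#' @export
pr_points <- function(scores, labels) {
  lab <- as_binary_labels(labels)
  if (sum(lab) == 0L) stop_data("no positive labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; lab <- lab[ord]
  last <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(lab)[last]
  pred_pos <- which(last)
  data.frame(threshold = s[last],
             recall = tp / sum(lab),
             precision = tp / pred_pos)
}

# Vertical averaging of fold curves on a common 101-point grid: for each
# grid x the mean across folds of the curve's y at that x (step
# interpolation, carrying the achievable value).
mean_curve <- function(curves, xcol, ycol, grid = seq(0, 1, length.out = 101L)) {
  ys <- vapply(curves, function(cv) {
    ord <- order(cv[[xcol]], cv[[ycol]])
    x <- cv[[xcol]][ord]; y <- cv[[ycol]][ord]
    stats::approx(x, y, xout = grid, method = "constant", f = 1,
                  ties = max, rule = 2)$y
  }, numeric(length(grid)))
  out <- data.frame(grid, rowMeans(ys))
  names(out) <- c(xcol, ycol)
  out
}
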