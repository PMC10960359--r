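#' Choose an operating cutoff on classifier scores
#'
#' Evaluates every candidate cutoff — each distinct observed score, plus
#' `Inf` for the all-negative rule — under the inclusive decision rule
#' "predict positive when score >= cutoff", and returns the cutoff
#' maximizing the requested criterion. `spec_times_sens` (specificity x
#' sensitivity) suits a balanced classification operating point;
#' `prec_plus_rec` (precision + recall) suits selecting a candidate list.
#' Ties are broken toward the smallest (most inclusive) cutoff.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels aligned to `scores`.
#' @param criterion `"spec_times_sens"` or `"prec_plus_rec"`.
#' @return An object of class `cutoff_result`: `cutoff`, `criterion`,
#'   `achieved`, `confusion` (tp/fp/tn/fn), `sensitivity`, `specificity`,
#'   `precision`, `recall`, and `n_selected` (genes at or above the
#'   cutoff).
#' @export
optimal_cutoff <- function(scores, labels,
                           criterion = c("spec_times_sens", "prec_plus_rec")) {
  criterion <- match.arg(criterion)
  lab <- as_binary_labels(labels)
  if (length(lab) != length(scores)) stop_data("scores and labels differ in length")
  n_pos <- sum(lab == 1L); n_neg <- sum(lab == 0L)
  if (n_pos == 0L || n_neg == 0L) stop_data("both classes must be present")

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- lab[ord]
  last <- !duplicated(s, fromLast = TRUE)
  tp <- c(0L, cumsum(l)[last])            # leading 0 = Inf cutoff (none selected)
  pred_pos <- c(0L, which(last))
  cand <- c(Inf, s[last])
  fp <- pred_pos - tp
  fn <- n_pos - tp
  tn <- n_neg - fp
  sens <- tp / n_pos
  spec <- tn / n_neg
  prec <- ifelse(pred_pos == 0L, 0, tp / pred_pos)
  value <- switch(criterion,
                  spec_times_sens = spec * sens,
                  prec_plus_rec = prec + sens)
  best_value <- max(value)
  winners <- which(value >= best_value - 1e-12)
  best <- winners[which.min(cand[winners])]
  structure(
    list(cutoff = cand[best], criterion = criterion, achieved = value[best],
         confusion = c(tp = tp[best], fp = fp[best], tn = tn[best], fn = fn[best]),
         sensitivity = sens[best], specificity = spec[best],
         precision = prec[best], recall = sens[best],
         n_selected = pred_pos[best]),
    class = "cutoff_result"
  )
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("<cutoff_result> %s: cutoff %.4g (criterion value %.4g); %d selected; tp=%d fp=%d tn=%d fn=%d\n",
              x$criterion, x$cutoff, x$achieved, x$n_selected,
              x$confusion["tp"], x$confusion["fp"], x$confusion["tn"],
              x$confusion["fn"]))
  invisible(x)
}

#' Compare a gene group's scores with random control genes
#'
#' Samples `n_controls` control genes from the scored universe excluding
#' the group and tests the group's scores against the controls' with a
#' two-sided Wilcoxon test. The default `rank_sum` variant treats the two
#' groups as independent samples (the controls are drawn independently of
#' the group); `signed_rank` pairs group and control genes by sample
#' index.
#'
#' @param universe_scores named numeric score vector over the full
#'   universe (e.g. from [predict_scores()]).
#' @param group character vector of gene names in the universe.
#' @param n_controls number of control genes to sample, default the
#'   group size (`signed_rank` requires equality).
#' @param controls optional explicit control gene names (no sampling).
#' @param rng_seed integer seed for control sampling.
#' @param test `"rank_sum"` (Mann-Whitney) or `"signed_rank"` (paired).
#' @return An object of class `group_rank_test`: `p_value`, `direction`
#'   (`"higher"`/`"lower"`/`"none"`, by median difference), `statistic`,
#'   `test`, `group_scores`, `control_genes`, `control_scores`.
#' @export
group_rank_test <- function(universe_scores, group,
                            n_controls = length(group), controls = NULL,
                            rng_seed = NULL,
                            test = c("rank_sum", "signed_rank")) {
  test <- match.arg(test)
  if (is.null(names(universe_scores))) stop_data("universe_scores must be named by gene")
  group <- unique(as.character(group))
  missing <- setdiff(group, names(universe_scores))
  if (length(missing)) {
    stop_data("group gene(s) not in the scored universe: ",
              paste(utils::head(missing, 10L), collapse = ", "))
  }
  if (!length(group)) stop_data("group is empty")
  if (is.null(controls)) {
    pool <- setdiff(names(universe_scores), group)
    if (length(pool) < n_controls) {
      stop_data(sprintf("control pool too small: need %d, have %d", n_controls, length(pool)))
    }
    controls <- with_rng(rng_seed, sample(pool, n_controls))
  } else {
    controls <- as.character(controls)
    missing <- setdiff(controls, names(universe_scores))
    if (length(missing)) stop_data("control gene(s) not in the scored universe")
  }
  gs <- unname(universe_scores[group])
  cs <- unname(universe_scores[controls])
  if (test == "signed_rank" && length(gs) != length(cs)) {
    stop_data("signed_rank pairing requires equal group and control sizes")
  }
  # ties (common in vote-fraction scores) silently use the normal approximation
  ht <- suppressWarnings(
    if (test == "rank_sum") {
      stats::wilcox.test(gs, cs, alternative = "two.sided")
    } else {
      stats::wilcox.test(gs, cs, paired = TRUE, alternative = "two.sided")
    }
  )
  md <- stats::median(gs) - stats::median(cs)
  structure(
    list(p_value = ht$p.value,
         direction = if (md > 0) "higher" else if (md < 0) "lower" else "none",
         statistic = unname(ht$statistic), test = test,
         group_scores = stats::setNames(gs, group),
         control_genes = controls,
         control_scores = stats::setNames(cs, controls)),
    class = "group_rank_test"
  )
}

#' @export
print.group_rank_test <- function(x, ...) {
  cat(sprintf("<group_rank_test> %s: group of %d scores %s than %d controls, p = %.4g\n",
              x$test, length(x$group_scores), x$direction,
              length(x$control_scores), x$p_value))
  invisible(x)
}
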