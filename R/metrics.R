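# Evaluation metric: area under the precision-recall curve, computed as
# average precision. Under extreme class imbalance AUPRC is far more
# informative than AUROC, and its value under random ranking approaches the
# positive prevalence, giving a natural chance baseline.

#' Area under the precision-recall curve (average precision)
#'
#' Uses the step-interpolated average-precision estimator: sort by
#' descending score and sum, over the positive examples, the precision at
#' each positive's rank, divided by the number of positives. Tied scores
#' are treated as one group and all positives in a group receive the
#' precision computed at the group's end, so the value does not depend on
#' the ordering of ties.
#'
#' @param labels binary 0/1 vector.
#' @param scores numeric score vector, higher means more likely positive.
#' @return average precision in `(0, 1]`.
#' @export
auprc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) {
    abort_shape("labels and scores must have equal length")
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels != 1)
  if (n_pos == 0 || n_neg == 0) {
    abort_metric("AUPRC undefined: need at least one positive and one negative label")
  }
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  # group boundaries: last index of each run of equal scores
  last_of_group <- which(c(s[-1] != s[-length(s)], TRUE))
  cum_pos <- cumsum(y)
  prec_at_end <- cum_pos[last_of_group] / last_of_group
  pos_in_group <- diff(c(0, cum_pos[last_of_group]))
  sum(pos_in_group * prec_at_end) / n_pos
}
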