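# Decision rules and metrics: frame-group majority voting, per-recording
# mode decisions, the dual-network agreement/rejection rule, and confusion
# based metrics (accuracy, macro precision/recall/F1).

#' Majority voting over consecutive frame groups
#'
#' Partitions an ordered sequence of frame-level decisions into consecutive
#' groups of `group_size` (the last group may be shorter) and returns each
#' group's modal label; ties are broken by the earliest-appearing tied label
#' within the group.
#'
#' @param labels character vector of frame decisions, in time order.
#' @param group_size frames per group (`m >= 1`); `m = 1` returns the input.
#' @return one label per group.
#' @examples
#' majority_vote(c("class1", "class1", "class3", "class1", "class5"), 5)
#' @export
majority_vote <- function(labels, group_size = 25) {
  if (length(labels) == 0) stopf("`labels` must be non-empty")
  if (!is_count(group_size)) stopf("`group_size` must be a positive integer")
  groups <- split(labels, (seq_along(labels) - 1) %/% group_size)
  unname(vapply(groups, modal_label, labels[[1]]))
}

#' Single decision for a whole recording
#'
#' The mode of all frame-by-frame decisions of one recording, with the same
#' earliest-appearance tie rule as [majority_vote()].
#'
#' @param frame_labels frame decisions for one recording.
#' @return a single label.
#' @export
vocalization_decision <- function(frame_labels) {
  if (length(frame_labels) == 0) stopf("`frame_labels` must be non-empty")
  modal_label(frame_labels)
}

#' Dual-network agreement decision
#'
#' Accepts a test only when the two networks output the same class; a
#' disagreement is a rejection (returned as `NA`). Recognition rates
#' downstream are computed over non-rejected tests only.
#'
#' @param label_a,label_b decisions from the two networks (vectorized).
#' @return the common label where the networks agree, `NA` (rejected)
#'   elsewhere.
#' @export
dual_decision <- function(label_a, label_b) {
  stopifnot(length(label_a) == length(label_b))
  ifelse(!is.na(label_a) & !is.na(label_b) & label_a == label_b,
         label_a, NA_character_)
}

#' Confusion matrix from truth/prediction pairs
#'
#' @param truth,prediction label vectors of equal length.
#' @param classes class order for the matrix (default: sorted union).
#' @return a `K x K` integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, prediction, classes = NULL) {
  stopifnot(length(truth) == length(prediction))
  if (is.null(classes)) classes <- sort(unique(c(truth, prediction)))
  table(factor(truth, levels = classes),
        factor(prediction, levels = classes)) |>
    unclass()
}

#' Metrics from a confusion matrix
#'
#' Accuracy is the ratio of correct predictions to the total number of
#' tests. Per-class precision is column-correct over column-total, recall is
#' row-correct over row-total, and `F1_i = 2 P_i R_i / (P_i + R_i)`; the
#' macro values are unweighted means over classes. A class never predicted
#' (empty column) gets precision 0; `P_i + R_i = 0` gives `F1_i = 0`.
#'
#' @param confusion `K x K` non-negative count matrix (rows = true class).
#' @param rejected number of rejected tests (dual-network evaluation).
#' @return an `eval_report`: confusion, `accuracy`, per-class tibble,
#'   `macro_precision`, `macro_recall`, `macro_f1`, `n_tests`, `rejected`.
#' @export
compute_metrics <- function(confusion, rejected = 0L) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stopf("Confusion matrix must be square")
  if (any(confusion < 0)) stopf("Confusion matrix entries must be non-negative")
  total <- sum(confusion)
  if (total <= 0) stopf("Confusion matrix has no observations")
  classes <- rownames(confusion) %||% as.character(seq_len(nrow(confusion)))
  correct <- diag(confusion)
  col_tot <- colSums(confusion)
  row_tot <- rowSums(confusion)
  precision <- ifelse(col_tot > 0, correct / col_tot, 0)
  recall <- ifelse(row_tot > 0, correct / row_tot, 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  structure(
    list(confusion = confusion,
         accuracy = sum(correct) / total,
         per_class = tibble(class = classes, precision = unname(precision),
                            recall = unname(recall), f1 = unname(f1),
                            n_true = unname(row_tot), n_predicted = unname(col_tot)),
         macro_precision = mean(precision),
         macro_recall = mean(recall),
         macro_f1 = mean(f1),
         n_tests = total + rejected,
         rejected = as.integer(rejected)),
    class = "eval_report"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %d tests%s | accuracy %.1f%% | macro P %.1f%% R %.1f%% F1 %.1f%%\n",
    x$n_tests,
    if (x$rejected > 0) sprintf(" (%d rejected)", x$rejected) else "",
    100 * x$accuracy, 100 * x$macro_precision, 100 * x$macro_recall, 100 * x$macro_f1))
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) x$per_class

#' @export
glance.eval_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, macro_precision = x$macro_precision,
         macro_recall = x$macro_recall, macro_f1 = x$macro_f1,
         n_tests = x$n_tests, rejected = x$rejected)
}
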