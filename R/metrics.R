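# Evaluation metrics: one-vs-one multiclass AUC (Hand-and-Till M measure),
# balanced accuracy, multiclass false discovery rate.

# Rank-based binary AUC: probability that a random positive outscores a
# random negative (ties count one half).
rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  n1 <- length(pos); n2 <- length(neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' One-vs-one multiclass AUC (Hand-and-Till M)
#'
#' For every unordered class pair (i, j), restricts to samples of those two
#' classes and computes A(i|j), the probability that a random class-i sample
#' receives a higher class-i score than a random class-j sample, and A(j|i)
#' analogously on the class-j scores; the pair value is their mean and the
#' overall measure the mean over pairs.  For two classes this reduces exactly
#' to the standard binary AUC.
#'
#' @param scores Numeric matrix of class scores (samples x classes, columns
#'   named by class).
#' @param labels Vector of true class labels.
#' @return List with `pairs` (data frame: class_i, class_j, auc) and `mean`.
#' @export
auc_one_vs_one <- function(scores, labels) {
  labels <- as.character(labels)
  classes <- colnames(scores)
  if (length(intersect(classes, unique(labels))) < 2L)
    stopf("need at least two classes present in labels")
  combs <- utils::combn(classes, 2L)
  out <- data.frame(class_i = combs[1L, ], class_j = combs[2L, ],
                    auc = NA_real_)
  for (k in seq_len(ncol(combs))) {
    i <- combs[1L, k]; j <- combs[2L, k]
    ri <- labels == i; rj <- labels == j
    if (!any(ri) || !any(rj)) {
      warnf("pair %s/%s skipped: class with zero samples", i, j)
      next
    }
    a_ij <- rank_auc(scores[ri, i], scores[rj, i])
    a_ji <- rank_auc(scores[rj, j], scores[ri, j])
    out$auc[k] <- (a_ij + a_ji) / 2
  }
  list(pairs = out, mean = mean(out$auc, na.rm = TRUE))
}

#' Balanced accuracy from a confusion matrix
#'
#' Mean of per-class recall (diagonal over row sum); rows are true classes.
#' Classes absent from the truth (zero row sum) are excluded with a warning.
#'
#' @param cm Square confusion matrix, rows = true classes, columns =
#'   predicted classes in the same order.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stopf("confusion matrix must be square")
  rs <- rowSums(cm)
  if (all(rs == 0)) stopf("empty-input error: all-zero confusion matrix")
  if (any(rs == 0))
    warnf("%d class(es) with zero true samples excluded", sum(rs == 0))
  mean(diag(cm)[rs > 0] / rs[rs > 0])
}

#' Multiclass false discovery rate from a confusion matrix
#'
#' Per predicted class c, FDR(c) = false predictions of c divided by all
#' predictions of c (1 - precision); the macro mean averages over classes
#' with at least one prediction (never-predicted classes are excluded with a
#' warning).
#'
#' @param cm Square confusion matrix, rows = true classes.
#' @return List with `per_class` (named vector) and `macro` mean.
#' @export
false_discovery_rate <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stopf("confusion matrix must be square")
  cs <- colSums(cm)
  fdr <- ifelse(cs > 0, (cs - diag(cm)) / cs, NA_real_)
  names(fdr) <- colnames(cm) %||% sprintf("class%d", seq_len(ncol(cm)))
  if (any(cs == 0))
    warnf("%d class(es) never predicted excluded from macro FDR", sum(cs == 0))
  list(per_class = fdr, macro = mean(fdr, na.rm = TRUE))
}

#' Percentage breakdown of class counts
#'
#' @param counts Named integer vector of per-class counts.
#' @param digits Decimal places for rounding (default 1).
#' @return Named vector of percentages summing to ~100.
#' @export
class_percentages <- function(counts, digits = 1L) {
  round(100 * counts / sum(counts), digits)
}
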