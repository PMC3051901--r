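# ROC / precision-recall / FDR-curve utilities. Ties are grouped: all
# examples sharing a score enter the confusion matrix together.

#' ROC curve with (partial) auROC
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels 0/1 (or -1/+1, or logical) class labels.
#' @param partial_fpr upper FPR bound of the partial auROC interval.
#' @return object of class `roc_curve`: thresholds, fpr, tpr, auroc,
#'   pauroc (raw area over \[0, partial_fpr\]) and pauroc_norm (divided by the
#'   interval width).
#' @export
roc <- function(scores, labels, partial_fpr = 0.3) {
  labels <- normalize_labels(labels)
  if (length(unique(labels)) < 2L) stop("ROC needs both classes")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  grp_last <- which(c(s[-1L] != s[-length(s)], TRUE))
  tp <- cumsum(l)[grp_last]
  fp <- cumsum(1 - l)[grp_last]
  P <- sum(l); N <- length(l) - P
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  thr <- c(Inf, s[grp_last])
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  pa <- partial_area(fpr, tpr, partial_fpr)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auroc = auroc,
                 pauroc = pa, pauroc_norm = pa / partial_fpr),
            class = "roc_curve")
}

partial_area <- function(fpr, tpr, bound) {
  if (bound >= max(fpr)) return(sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2))
  keep <- fpr <= bound
  x <- fpr[keep]; y <- tpr[keep]
  # interpolate the curve at the bound
  i <- max(which(keep))
  if (fpr[i] < bound && i < length(fpr)) {
    frac <- (bound - fpr[i]) / (fpr[i + 1L] - fpr[i])
    x <- c(x, bound)
    y <- c(y, tpr[i] + frac * (tpr[i + 1L] - tpr[i]))
  }
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' Area under the ROC curve
#' @inheritParams roc
#' @return auROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) roc(scores, labels)$auroc

#' Precision-recall curve
#'
#' @inheritParams roc
#' @return object of class `pr_curve`: thresholds, recall, precision.
#' @export
precision_recall <- function(scores, labels) {
  labels <- normalize_labels(labels)
  if (sum(labels) == 0L) stop("precision-recall needs positives")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  grp_last <- which(c(s[-1L] != s[-length(s)], TRUE))
  tp <- cumsum(l)[grp_last]
  n_pred <- grp_last
  structure(list(thresholds = s[grp_last],
                 recall = tp / sum(l),
                 precision = tp / n_pred),
            class = "pr_curve")
}

#' Empirical FDR as a function of the score cutoff
#'
#' FDR(c) = 1 - precision among predictions scoring >= c.
#'
#' @inheritParams roc
#' @return data.frame with cutoff and fdr, one row per distinct score.
#' @export
estimate_fdr_curve <- function(scores, labels) {
  pr <- precision_recall(scores, labels)
  data.frame(cutoff = pr$thresholds, fdr = 1 - pr$precision)
}

normalize_labels <- function(labels) {
  l <- as.numeric(labels)
  l[l < 0] <- 0
  if (!all(l %in% c(0, 1))) stop("labels must be binary")
  l
}
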