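#' ROC area under the curve
#'
#' Computed by the rank (Mann-Whitney) formulation with midranks for ties:
#' the probability that a random positive outscores a random negative, with
#' ties counted half.  Equivalent to the trapezoidal area under the ROC
#' curve over all score thresholds.
#'
#' @param labels 0/1 vector (both classes present).
#' @param scores numeric scores, higher = more positive.
#' @return AUC in \code{[0, 1]}.
#' @export
rocAuc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)  # midranks
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics at the 0.5 decision threshold
#'
#' @param labels 0/1 true labels.
#' @param flags 0/1 (or logical) predictions.
#' @param fold optional fold identifier carried into the result.
#' @return one-row data.frame: tp, fp, tn, fn, sensitivity, specificity,
#'   fpr, fnr, accuracy, fold.
#' @examples
#' confusionMetrics(rep(c(1, 0), c(100, 100)),
#'                  rep(c(1, 0, 0, 1), c(90, 10, 89, 11)))
#' @export
confusionMetrics <- function(labels, flags, fold = NA_integer_) {
  if (length(labels) == 0) stop("empty input")
  stopifnot(length(labels) == length(flags))
  flags <- as.integer(flags)
  stopifnot(all(labels %in% c(0, 1)), all(flags %in% c(0, 1)))
  tp <- sum(labels == 1 & flags == 1)
  fp <- sum(labels == 0 & flags == 1)
  tn <- sum(labels == 0 & flags == 0)
  fn <- sum(labels == 1 & flags == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  data.frame(tp = tp, fp = fp, tn = tn, fn = fn,
             sensitivity = sens, specificity = spec,
             fpr = 1 - spec, fnr = 1 - sens,
             accuracy = (tp + tn) / length(labels), fold = fold)
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum statistic of the first sample (midranks for ties).  The
#' two-sided p-value is exact -- by enumeration of all
#' \code{choose(n_a + n_b, n_a)} rank assignments -- when
#' \code{n_a + n_b <= exactLimit}, and a normal approximation with tie
#' correction and continuity correction otherwise.
#'
#' @param a,b numeric samples.
#' @param exactLimit maximum pooled size for the exact path (default 12).
#' @return list with \code{statistic} (rank sum of \code{a}), \code{p}
#'   (two-sided) and \code{method}.
#' @examples
#' wilcoxonRankSum(c(4, 5, 6), c(1, 2, 3))$p   # 2/20 = 0.1
#' @export
wilcoxonRankSum <- function(a, b, exactLimit = 12L) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  na <- length(a)
  nb <- length(b)
  n <- na + nb
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  EW <- na * (n + 1) / 2
  if (n <= exactLimit) {
    sums <- utils::combn(n, na, FUN = function(i) sum(r[i]))
    p <- mean(abs(sums - EW) >= abs(W - EW) - 1e-12)
    list(statistic = W, p = p, method = "exact enumeration")
  } else {
    ties <- table(r)
    tieCorr <- sum(ties^3 - ties) / (n * (n - 1))
    V <- na * nb / 12 * ((n + 1) - tieCorr)
    z <- (W - EW - sign(W - EW) * 0.5) / sqrt(V)
    list(statistic = W, p = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal approximation")
  }
}

#' Cross-validation report
#'
#' Mean and sample standard deviation (n - 1) of each metric across folds;
#' optionally compares two models' per-fold AUCs with the rank-sum test.
#'
#' @param results data.frame of per-fold metrics (rows = folds), e.g. rows
#'   from [confusionMetrics()] with an \code{auc} column added.
#' @param other optional second model's per-fold results with matching fold
#'   count.
#' @return list with \code{summary} (data.frame metric/mean/sd) and, when
#'   \code{other} is given, \code{comparison} (rank-sum test on per-fold
#'   AUCs).
#' @export
crossvalReport <- function(results, other = NULL) {
  if (nrow(results) < 2) stop("need at least 2 folds")
  metrics <- setdiff(names(results),
                     c("fold", "tp", "fp", "tn", "fn"))
  metrics <- metrics[vapply(results[metrics], is.numeric, TRUE)]
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(results[[m]]), 0),
    sd = vapply(metrics, function(m) stats::sd(results[[m]]), 0),
    row.names = NULL)
  out <- list(summary = summary)
  if (!is.null(other)) {
    if (nrow(other) != nrow(results))
      stop("fold counts differ between the two models")
    if (!("auc" %in% names(results) && "auc" %in% names(other)))
      stop("per-fold 'auc' column required for a model comparison")
    out$comparison <- wilcoxonRankSum(results$auc, other$auc)
  }
  out
}
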