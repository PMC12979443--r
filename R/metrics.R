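# Evaluation stack for scored binary outcomes: threshold confusion metrics,
# rank-based ROC-AUC, average-precision PR-AUC, decision-curve net benefit,
# and calibration with the Brier score. Scores are probabilities in [0, 1];
# the positive call is `score >= threshold` (inclusive) throughout.

check_scores <- function(y, scores) {
  if (length(y) == 0L) stop("empty outcome vector")
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(scores) != length(y)) stop("scores and outcomes differ in length")
  if (any(!is.finite(scores))) stop("non-finite scores")
}

#' Threshold confusion-matrix metrics
#'
#' Dichotomizes scores at `threshold` (positive call when
#' `score >= threshold`) and returns sensitivity (SEN), precision (PRE),
#' specificity (SPE), accuracy (ACC) and F1 together with the confusion
#' counts. An empty denominator (e.g. no predicted positives) yields 0 for
#' the affected metric and sets the `degenerate` flag.
#'
#' @param y Binary 0/1 outcome vector.
#' @param scores Numeric scores in \[0, 1\].
#' @param threshold Decision threshold, default 0.5.
#' @return Object of class `"metric_report"`: `PRE`, `SEN`, `SPE`, `ACC`,
#'   `F1`, `counts` (TP/FP/FN/TN), `threshold`, `degenerate`.
#' @examples
#' confusion_metrics(c(1, 1, 1, 1, 0, 0), c(.9, .8, .7, .2, .6, .1))
#' @export
confusion_metrics <- function(y, scores, threshold = 0.5) {
  check_scores(y, scores)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  degenerate <- FALSE
  div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  sen <- div(tp, tp + fn); spe <- div(tn, tn + fp); pre <- div(tp, tp + fp)
  acc <- (tp + tn) / length(y)
  f1 <- if (pre + sen > 0) 2 * pre * sen / (pre + sen) else { degenerate <- TRUE; 0 }
  structure(list(PRE = pre, SEN = sen, SPE = spe, ACC = acc, F1 = f1,
                 counts = c(TP = tp, FP = fp, FN = fn, TN = tn),
                 threshold = threshold, degenerate = degenerate),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("PRE %.4f  SEN %.4f  SPE %.4f  ACC %.4f  F1 %.4f  (thr %.2f)\n",
              x$PRE, x$SEN, x$SPE, x$ACC, x$F1, x$threshold))
  cat(sprintf("counts: TP %d FP %d FN %d TN %d%s\n",
              x$counts["TP"], x$counts["FP"], x$counts["FN"], x$counts["TN"],
              if (x$degenerate) "  [degenerate denominator]" else ""))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability: the probability a
#' random positive outscores a random negative, ties counted one half
#' (rank formulation, exactly the exhaustive pairwise comparison).
#'
#' @inheritParams confusion_metrics
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(y, scores) {
  check_scores(y, scores)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("ROC-AUC requires both outcome classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: thresholds descend through the unique score
#' values; each step contributes its recall increment times the precision at
#' that threshold. With all scores tied this reduces to the prevalence.
#'
#' @inheritParams confusion_metrics
#' @return PR-AUC in \[0, 1\].
#' @export
pr_auc <- function(y, scores) {
  check_scores(y, scores)
  n1 <- sum(y == 1)
  if (n1 == 0) stop("PR-AUC requires at least one positive")
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0; prev_recall <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(y[sel] == 1)
    precision <- tp / sum(sel)
    recall <- tp / n1
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

#' Decision-curve analysis net benefit
#'
#' Net benefit of acting on the model at threshold probability `pt`:
#' `NB(pt) = TP/N - FP/N * pt / (1 - pt)` with positives called at
#' `score >= pt`, compared against treating everyone
#' (`prevalence - (1 - prevalence) * pt / (1 - pt)`) and treating no one
#' (zero). The default grid spans 0.01-0.99 in steps of 0.01.
#'
#' @inheritParams confusion_metrics
#' @param thresholds Threshold-probability grid, strictly inside (0, 1).
#' @return Object of class `"dca_curve"`: `thresholds`, `nb_model`,
#'   `nb_all`, `nb_none`, `prevalence`.
#' @export
decision_curve <- function(y, scores, thresholds = seq(0.01, 0.99, by = 0.01)) {
  check_scores(y, scores)
  if (any(thresholds <= 0) || any(thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1)")
  n <- length(y); prev <- mean(y)
  odds <- thresholds / (1 - thresholds)
  nb_model <- vapply(seq_along(thresholds), function(i) {
    sel <- scores >= thresholds[i]
    sum(y[sel] == 1) / n - sum(y[sel] == 0) / n * odds[i]
  }, numeric(1))
  structure(list(thresholds = thresholds, nb_model = nb_model,
                 nb_all = prev - (1 - prev) * odds,
                 nb_none = rep(0, length(thresholds)),
                 prevalence = prev),
            class = "dca_curve")
}

#' @export
plot.dca_curve <- function(x, highlight = c(0.22, 0.76), ...) {
  rng <- range(c(x$nb_model, x$nb_all, 0))
  plot(x$thresholds, x$nb_model, type = "l", ylim = rng,
       xlab = "threshold probability", ylab = "net benefit", ...)
  lines(x$thresholds, x$nb_all, lty = 2)
  abline(h = 0, lty = 3)
  if (!is.null(highlight)) abline(v = highlight, col = "grey", lty = 3)
  legend("topright", c("model", "treat all", "treat none"),
         lty = c(1, 2, 3), bty = "n")
  invisible(x)
}

#' Calibration curve and Brier score
#'
#' Bins predictions into `n_bins` equal-width bins on \[0, 1\] (last bin
#' closed) and reports the mean prediction and observed outcome rate per
#' bin, plus the Brier score (mean squared difference between score and
#' outcome; lower is better).
#'
#' @inheritParams confusion_metrics
#' @param n_bins Number of equal-width bins, default 10.
#' @return Object of class `"calibration_report"`: `bin_edges`,
#'   `bin_mean_pred`, `bin_obs_rate`, `bin_n`, `brier`.
#' @export
calibration <- function(y, scores, n_bins = 10) {
  check_scores(y, scores)
  if (any(scores < 0 | scores > 1)) stop("calibration needs scores in [0, 1]")
  edges <- seq(0, 1, length.out = n_bins + 1)
  idx <- pmin(pmax(findInterval(scores, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  bin_n <- tabulate(idx, n_bins)
  bin_mean <- rep(NA_real_, n_bins); bin_obs <- rep(NA_real_, n_bins)
  for (b in which(bin_n > 0)) {
    bin_mean[b] <- mean(scores[idx == b])
    bin_obs[b] <- mean(y[idx == b])
  }
  structure(list(bin_edges = edges, bin_mean_pred = bin_mean,
                 bin_obs_rate = bin_obs, bin_n = bin_n,
                 brier = mean((scores - y)^2)),
            class = "calibration_report")
}

#' @export
plot.calibration_report <- function(x, ...) {
  ok <- x$bin_n > 0
  plot(x$bin_mean_pred[ok], x$bin_obs_rate[ok], xlim = 0:1, ylim = 0:1,
       xlab = "mean predicted probability", ylab = "observed rate",
       type = "b", ...)
  abline(0, 1, lty = 2)
  legend("topleft", sprintf("Brier %.3f", x$brier), bty = "n")
  invisible(x)
}

#' Full evaluation report for a scored test set
#'
#' Convenience wrapper combining [confusion_metrics()], [roc_auc()],
#' [pr_auc()], [decision_curve()] and [calibration()].
#'
#' @inheritParams confusion_metrics
#' @return List with `metrics`, `roc_auc`, `pr_auc`, `dca`, `calibration`.
#' @export
evaluate_scores <- function(y, scores, threshold = 0.5) {
  list(metrics = confusion_metrics(y, scores, threshold),
       roc_auc = roc_auc(y, scores),
       pr_auc = pr_auc(y, scores),
       dca = decision_curve(y, scores),
       calibration = calibration(y, scores))
}
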