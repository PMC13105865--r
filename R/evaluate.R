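#' Confusion matrix with per-class precision/recall/F1
#'
#' @param truth,estimate Factors (or coercibles) on the same level set.
#' @param levels Optional explicit class levels.
#' @return A `class_confusion` object holding the K x K count matrix
#'   (rows = truth), the row-normalized view, and a per-class metric tibble
#'   (`precision`, `recall`, `f1`, `support`). F1 is defined as 0 when
#'   precision + recall is 0.
#' @export
confusion_and_prf <- function(truth, estimate, levels = NULL) {
  levels <- levels %||% base::levels(as.factor(truth))
  truth <- factor(truth, levels = levels)
  estimate <- factor(estimate, levels = levels)
  cm <- table(truth = truth, estimate = estimate)
  cm <- matrix(as.integer(cm), nrow(cm), ncol(cm), dimnames = dimnames(cm))
  support <- unname(rowSums(cm))
  pred_n <- unname(colSums(cm))
  tp <- unname(diag(cm))
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  per_class <- tibble::tibble(
    class = levels, support = support,
    precision = precision, recall = recall,
    f1 = f1_score(precision, recall)
  )
  norm <- cm / ifelse(support > 0, support, 1)
  structure(
    list(counts = cm, row_normalized = norm, per_class = per_class,
         n = sum(cm)),
    class = "class_confusion"
  )
}

#' @export
print.class_confusion <- function(x, ...) {
  cat("<class_confusion>\n")
  print(round(x$row_normalized, 3))
  invisible(x)
}

#' @export
tidy.class_confusion <- function(x, ...) {
  x$per_class
}

#' Per-class F1 from precision and recall
#'
#' `F1 = 2 P R / (P + R)`, with the 0/0 case defined as 0. Vectorized.
#' @param precision,recall Numeric vectors in \[0, 1\].
#' @return Numeric vector of F1 scores.
#' @export
f1_score <- function(precision, recall) {
  s <- precision + recall
  ifelse(s > 0, 2 * precision * recall / s, 0)
}

#' Macro and support-weighted F1
#'
#' Macro-F1 is the unweighted mean of the per-class F1 scores; Weighted-F1
#' weights each class by its support share.
#' @param per_class_f1 Numeric vector of class F1 scores.
#' @param supports Class supports n_k.
#' @return Named list with `macro_f1` and `weighted_f1`.
#' @export
macro_weighted_f1 <- function(per_class_f1, supports) {
  list(
    macro_f1 = mean(per_class_f1),
    weighted_f1 = sum(supports / sum(supports) * per_class_f1)
  )
}

#' Balanced accuracy and multiclass Matthews correlation
#'
#' Balanced accuracy is the mean per-class recall. MCC uses the generalized
#' multiclass formula on confusion counts.
#' @param cm A `class_confusion` or raw K x K count matrix (rows = truth).
#' @return Scalar metric.
#' @export
balanced_accuracy <- function(cm) {
  if (inherits(cm, "class_confusion")) cm <- cm$counts
  support <- rowSums(cm)
  mean(diag(cm)[support > 0] / support[support > 0])
}

#' @rdname balanced_accuracy
#' @export
multiclass_mcc <- function(cm) {
  if (inherits(cm, "class_confusion")) cm <- cm$counts
  cm <- matrix(as.numeric(cm), nrow(cm))
  s <- sum(cm)
  c0 <- sum(diag(cm))
  t_k <- rowSums(cm)
  p_k <- colSums(cm)
  num <- c0 * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) return(0)
  num / den
}

# Binary ROC AUC via the rank (Mann-Whitney) statistic with tie correction.
binary_auroc <- function(score, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Average precision (step-wise integral of the precision-recall curve).
binary_auprc <- function(score, positive) {
  n1 <- sum(positive)
  if (n1 == 0L || all(positive)) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  pos <- positive[ord]
  tp <- cumsum(pos)
  precision <- tp / seq_along(pos)
  recall <- tp / n1
  sum(precision * diff(c(0, recall)))
}

#' Macro one-vs-rest AUROC and AUPRC
#'
#' Each class in turn is treated as positive; classes without at least one
#' positive and one negative in `truth` are excluded from the macro mean
#' (with a message).
#'
#' @param prob Samples x classes probability matrix (columns named by
#'   class) or a prediction tibble with `.pred_<class>` columns.
#' @param truth Factor of true classes.
#' @return Named list with `auroc` and `auprc`.
#' @export
ovr_macro_auc <- function(prob, truth) {
  prob <- prob_matrix(prob, levels(as.factor(truth)))
  truth <- factor(truth, levels = colnames(prob))
  aucs <- prs <- numeric(0)
  for (k in colnames(prob)) {
    pos <- truth == k
    if (sum(pos) == 0L || sum(!pos) == 0L) {
      inform(sprintf("class %s absent from one side; excluded from macro AUC", k))
      next
    }
    aucs <- c(aucs, binary_auroc(prob[, k], pos))
    prs <- c(prs, binary_auprc(prob[, k], pos))
  }
  list(auroc = mean(aucs), auprc = mean(prs))
}

prob_matrix <- function(prob, levels) {
  if (is.data.frame(prob)) {
    cols <- paste0(".pred_", levels)
    stopifnot(all(cols %in% names(prob)))
    prob <- as.matrix(prob[, cols])
    colnames(prob) <- levels
  }
  if (is.null(colnames(prob))) colnames(prob) <- levels
  prob
}

#' Full discrimination metric report
#'
#' Accuracy, balanced accuracy, MCC, Macro-F1, Weighted-F1, and macro
#' one-vs-rest AUROC/AUPRC in one row.
#'
#' @param truth Factor of true classes.
#' @param estimate Factor of predicted classes.
#' @param prob Optional probability matrix / `.pred_` tibble for the AUC
#'   metrics.
#' @return One-row tibble.
#' @export
metric_report <- function(truth, estimate, prob = NULL) {
  cm <- confusion_and_prf(truth, estimate)
  mw <- macro_weighted_f1(cm$per_class$f1, cm$per_class$support)
  out <- tibble::tibble(
    accuracy = sum(diag(cm$counts)) / cm$n,
    bal_accuracy = balanced_accuracy(cm),
    mcc = multiclass_mcc(cm),
    macro_f1 = mw$macro_f1,
    weighted_f1 = mw$weighted_f1
  )
  if (!is.null(prob)) {
    auc <- ovr_macro_auc(prob, truth)
    out$auroc <- auc$auroc
    out$auprc <- auc$auprc
  }
  out
}

#' Calibration report: reliability bins, ECE, Brier score, NLL
#'
#' Confidence is the maximum predicted probability. Samples are assigned to
#' `bins` equal-width confidence bins on (0, 1]; the expected calibration
#' error is the occupancy-weighted absolute gap between per-bin accuracy
#' and per-bin mean confidence. The Brier score is the mean over samples of
#' the squared deviation between the probability vector and the one-hot
#' label, summed over classes; NLL is the mean negative log-probability of
#' the true class.
#'
#' @param prob Samples x classes probability matrix or `.pred_` tibble.
#' @param truth Factor of true classes.
#' @param bins Number of equal-width confidence bins (default 15).
#' @return A `calibration_report`: bin tibble (`bin`, `lower`, `upper`,
#'   `occupancy`, `confidence`, `accuracy`) plus scalars `ece`, `brier`,
#'   `nll`, `n`.
#' @export
calibration_report <- function(prob, truth, bins = 15L) {
  truth <- as.factor(truth)
  prob <- prob_matrix(prob, levels(truth))
  stopifnot(all(levels(truth) %in% colnames(prob)))
  n <- nrow(prob)
  conf <- apply(prob, 1L, max)
  pred <- colnames(prob)[max.col(prob)]
  correct <- pred == as.character(truth)
  # bins are ((m-1)/M, m/M]; confidence is > 0 so every sample lands in one
  bin_of <- pmax(1L, pmin(bins, ceiling(conf * bins - 1e-12)))
  occupancy <- as.integer(tabulate(bin_of, bins))
  confidence <- vapply(seq_len(bins), function(m) {
    if (occupancy[m] == 0L) NA_real_ else mean(conf[bin_of == m])
  }, 0)
  accuracy <- vapply(seq_len(bins), function(m) {
    if (occupancy[m] == 0L) NA_real_ else mean(correct[bin_of == m])
  }, 0)
  bin_tbl <- tibble::tibble(
    bin = seq_len(bins), lower = (seq_len(bins) - 1) / bins,
    upper = seq_len(bins) / bins, occupancy = occupancy,
    confidence = confidence, accuracy = accuracy
  )
  occ <- bin_tbl$occupancy
  ece <- sum(occ[occ > 0] / n *
               abs(bin_tbl$accuracy[occ > 0] - bin_tbl$confidence[occ > 0]))
  onehot <- matrix(0, n, ncol(prob))
  onehot[cbind(seq_len(n), as.integer(truth))] <- 1
  brier <- mean(rowSums((prob - onehot)^2))
  nll <- -mean(log(pmax(prob[cbind(seq_len(n), as.integer(truth))], 1e-300)))
  structure(
    list(bins = bin_tbl, ece = ece, brier = brier, nll = nll, n = n,
         n_bins = bins),
    class = "calibration_report"
  )
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> ECE %.4f, Brier %.4f, NLL %.4f (n = %d, %d bins)\n",
              x$ece, x$brier, x$nll, x$n, x$n_bins))
  invisible(x)
}

#' @export
tidy.calibration_report <- function(x, ...) x$bins

#' @export
glance.calibration_report <- function(x, ...) {
  tibble::tibble(ece = x$ece, brier = x$brier, nll = x$nll, n = x$n)
}

#' Corrected repeated cross-validation t-test
#'
#' Paired comparison of two methods over the k x r fold-level metric
#' differences, using the variance correction for repeated cross-validation
#' (the naive variance is inflated by the test-to-train ratio `rho`,
#' 1/4 for five-fold CV). Zero-variance differences yield the degenerate
#' p of exactly 0 (nonzero mean) or 1 (zero mean) with a warning, not NaN.
#'
#' @param diffs Numeric vector of per-(repeat, fold) metric differences.
#' @param k,r Folds and repeats (defaults 5, 5).
#' @param rho Test-to-train ratio (default 0.25).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A `paired_comparison`: mean difference, corrected standard
#'   error, t statistic, two-sided p, confidence interval, df.
#' @export
nadeau_bengio_test <- function(diffs, k = 5L, r = 5L, rho = 0.25,
                               conf_level = 0.95) {
  n <- length(diffs)
  stopifnot(n == k * r)
  dbar <- mean(diffs)
  s2 <- var(diffs)
  df <- n - 1L
  if (s2 == 0) {
    warn("zero-variance differences: degenerate corrected t-test")
    p <- if (dbar == 0) 1 else 0
    t_stat <- if (dbar == 0) 0 else sign(dbar) * Inf
    ci <- c(dbar, dbar)
    se <- 0
  } else {
    se <- sqrt((1 / n + rho) * s2)
    t_stat <- dbar / se
    p <- 2 * pt(-abs(t_stat), df)
    tcrit <- qt(1 - (1 - conf_level) / 2, df)
    ci <- dbar + c(-1, 1) * tcrit * se
  }
  structure(
    list(mean_diff = dbar, se = se, statistic = t_stat, p_value = p,
         conf_low = ci[1], conf_high = ci[2], df = df, rho = rho,
         k = k, r = r, n = n),
    class = "paired_comparison"
  )
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(
    "<paired_comparison> mean diff %.4f, t(%d) = %.3f, p = %.4g, %d%% CI [%.4f, %.4f]\n",
    x$mean_diff, x$df, x$statistic, x$p_value, 95L, x$conf_low, x$conf_high
  ))
  invisible(x)
}

#' @export
tidy.paired_comparison <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_diff, statistic = x$statistic, p.value = x$p_value,
    conf.low = x$conf_low, conf.high = x$conf_high, df = x$df, rho = x$rho
  )
}

#' Relative ablation drop in percent
#'
#' `100 * (a_full - a_variant) / a_full`: the percentage of the full
#' model's metric lost by an ablation variant.
#' @param a_full,a_variant Metric values of the full model and the variant.
#' @return Relative drop in percent.
#' @export
rel_delta <- function(a_full, a_variant) {
  100 * (a_full - a_variant) / a_full
}

#' Evaluate an out-of-fold prediction table
#'
#' Computes the per-(repeat, fold) metric reports and their means, plus an
#' optional pooled calibration report, from the OOF tibble of [xonet_cv()].
#'
#' @param oof OOF tibble with `label`, `.pred_class`, `.pred_<class>`
#'   columns, `repeat_id`, `fold`.
#' @param bins Calibration bin count.
#' @return List with `per_fold` tibble, `summary` one-row tibble (mean over
#'   folds), and `calibration` report over all OOF rows.
#' @export
evaluate_oof <- function(oof, bins = 15L) {
  lev <- levels(oof$label)
  per_fold <- oof |>
    dplyr::group_by(.data$repeat_id, .data$fold) |>
    dplyr::group_modify(function(df, key) {
      metric_report(df$label, df$.pred_class, df)
    }) |>
    dplyr::ungroup()
  summary <- per_fold |>
    dplyr::summarise(dplyr::across(-c("repeat_id", "fold"), mean))
  calib <- calibration_report(oof, oof$label, bins = bins)
  list(per_fold = per_fold, summary = summary, calibration = calib)
}
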