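#' Apply a missing-modality scenario to a batch
#'
#' Zeroes the standardized features of the masked modalities and clears the
#' corresponding rows of the modality mask, so those modalities are also
#' excluded from attention readout. Model parameters are untouched — the
#' scenario is purely an inference-time intervention. Idempotent; the empty
#' scenario is the identity.
#'
#' @param batch A `patient_batch`.
#' @param drop Character subset of `c("g", "c", "m")` to mask (empty vector
#'   = no-op). At least one modality must remain.
#' @return The masked `patient_batch`.
#' @export
apply_missingness <- function(batch, drop = character(0)) {
  stopifnot(all(drop %in% c("g", "c", "m")))
  if (length(setdiff(c("g", "c", "m"), drop)) == 0L) {
    abort("at least one modality must remain present")
  }
  for (t in drop) {
    batch$X[[t]][] <- 0
    batch$mask[t, ] <- FALSE
  }
  batch
}

#' Missingness scenarios of the robustness protocol
#'
#' The named scenarios evaluated at inference time: full data, each single
#' modality absent, and the severe-loss setting where only mRNA remains.
#' @return Named list of modality subsets to mask.
#' @export
missingness_scenarios <- function() {
  list(
    "full" = character(0),
    "no_mrna" = "g",
    "no_cpg" = "c",
    "no_mirna" = "m",
    "mrna_only" = c("c", "m")
  )
}

#' Choose an abstention threshold on validation confidences
#'
#' Conservative rule: the largest threshold whose validation coverage
#' (fraction of samples with max-probability at or above the threshold)
#' still reaches the target. Equivalently, the `ceiling(target * n)`-th
#' largest validation confidence. Fixed before any test data is touched.
#'
#' @param val_conf Numeric vector of validation max-probabilities, or a
#'   probability matrix / `.pred_` tibble (row maxima are taken).
#' @param target_coverage Desired accepted fraction in (0, 1].
#' @return Scalar threshold tau.
#' @export
choose_threshold <- function(val_conf, target_coverage) {
  stopifnot(target_coverage > 0, target_coverage <= 1)
  if (is.matrix(val_conf) || is.data.frame(val_conf)) {
    val_conf <- apply(prob_matrix_any(val_conf), 1L, max)
  }
  n <- length(val_conf)
  sorted <- sort(val_conf, decreasing = TRUE)
  sorted[min(n, ceiling(target_coverage * n))]
}

prob_matrix_any <- function(prob) {
  if (is.data.frame(prob)) {
    prob <- as.matrix(prob[, grepl("^\\.pred_", names(prob)) &
                             names(prob) != ".pred_class"])
  }
  prob
}

#' Coverage-risk curve for selective prediction
#'
#' For each threshold, coverage is the accepted fraction (confidence at or
#' above the threshold) and risk is the error rate among accepted samples
#' (undefined where coverage is zero). Coverage is monotone non-increasing
#' in the threshold, and risk at coverage 1 equals one minus accuracy.
#'
#' @param prob Probability matrix or `.pred_` tibble for the test samples.
#' @param truth Factor of true classes.
#' @param tau_grid Thresholds to evaluate (default: sorted unique
#'   confidences plus 0).
#' @return Tibble with `tau`, `coverage`, `risk`, `n_accepted`.
#' @export
coverage_risk_curve <- function(prob, truth, tau_grid = NULL) {
  truth <- as.factor(truth)
  pm <- prob_matrix(prob, levels(truth))
  conf <- apply(pm, 1L, max)
  pred <- colnames(pm)[max.col(pm)]
  correct <- pred == as.character(truth)
  tau_grid <- tau_grid %||% sort(unique(c(0, conf)))
  purrr::map_dfr(tau_grid, function(tau) {
    acc <- conf >= tau
    tibble::tibble(
      tau = tau, coverage = mean(acc), n_accepted = sum(acc),
      risk = if (sum(acc) > 0) mean(!correct[acc]) else NA_real_
    )
  })
}

#' Selective operating points at pre-specified target coverages
#'
#' Thresholds are chosen on validation confidences, then applied unchanged
#' to the test fold; realized coverage and risk are reported per target.
#'
#' @param val_prob Validation probability matrix / `.pred_` tibble.
#' @param test_prob Test probability matrix / `.pred_` tibble.
#' @param test_truth Factor of test labels.
#' @param targets Target coverages (default 0.90, 0.80, 0.70).
#' @return Tibble with `target_coverage`, `tau`, `coverage`, `risk`.
#' @export
selective_operating_points <- function(val_prob, test_prob, test_truth,
                                       targets = c(0.90, 0.80, 0.70)) {
  purrr::map_dfr(targets, function(tg) {
    tau <- choose_threshold(val_prob, tg)
    cr <- coverage_risk_curve(test_prob, test_truth, tau_grid = tau)
    tibble::tibble(target_coverage = tg, tau = tau,
                   coverage = cr$coverage, risk = cr$risk)
  })
}

#' Missing-modality robustness evaluation
#'
#' Predicts a labelled batch under each scenario with fixed model
#' parameters and reports discrimination plus calibration metrics per
#' scenario.
#'
#' @param fit A `xonet_fit`.
#' @param batch A labelled `patient_batch`.
#' @param scenarios Named list of modality subsets (default
#'   [missingness_scenarios()]).
#' @param bins Calibration bin count.
#' @return Tibble: one row per scenario with metric columns.
#' @export
evaluate_missingness <- function(fit, batch, scenarios = missingness_scenarios(),
                                 bins = 15L) {
  truth <- factor(fit$classes[batch$y], levels = fit$classes)
  purrr::imap_dfr(scenarios, function(drop, name) {
    b <- apply_missingness(batch, drop)
    pr <- t(predict_probs(fit, b))
    colnames(pr) <- fit$classes
    est <- factor(fit$classes[max.col(pr)], levels = fit$classes)
    rep <- metric_report(truth, est, pr)
    cal <- calibration_report(pr, truth, bins = bins)
    dplyr::bind_cols(
      tibble::tibble(scenario = name,
                     masked = paste(drop, collapse = "+")),
      rep, tibble::tibble(ece = cal$ece, brier = cal$brier, nll = cal$nll)
    )
  })
}

#' Site-held-out generalization protocol
#'
#' For each site in turn, all of that site's samples are held out for
#' testing; standardization, inner validation and early stopping use only
#' the remaining sites. Sites with fewer samples than the number of classes
#' are skipped with a warning. Summaries report the mean and the worst
#' (minimum) metric across held-out sites.
#'
#' @param graph A `hetero_graph`.
#' @param expr,probe_beta,mirna Raw cohort matrices.
#' @param labels Factor of subtype labels.
#' @param sites Character/factor site label per sample.
#' @param config A [xonet_config()].
#' @param seed Root seed.
#' @param ... Passed to [xonet_fit()].
#' @return List with `per_site` metric tibble and `summary` (mean and
#'   worst-site rows).
#' @export
site_heldout_evaluate <- function(graph, expr, probe_beta, mirna, labels,
                                  sites, config = xonet_config(), seed = 1L,
                                  ...) {
  labels <- as.factor(labels)
  sites <- as.character(sites)
  sample_ids <- rownames(expr) %||% as.character(seq_along(labels))
  cbeta_raw <- summarize_cluster_methylation(probe_beta, graph$nodes$cpg)
  res <- list()
  for (s in sort(unique(sites))) {
    test_idx <- which(sites == s)
    if (length(test_idx) < config$num_classes) {
      warn(sprintf("site %s has %d samples (< %d classes); skipped",
                   s, length(test_idx), config$num_classes))
      next
    }
    tr <- which(sites != s)
    std <- list(
      g = fit_standardizer(expr[tr, , drop = FALSE]),
      c = fit_standardizer(cbeta_raw[tr, , drop = FALSE]),
      m = fit_standardizer(mirna[tr, , drop = FALSE])
    )
    batch <- prepare_batch(
      graph,
      apply_standardizer(std$g, expr),
      apply_standardizer(std$c, cbeta_raw),
      apply_standardizer(std$m, mirna),
      labels = labels, sample_ids = sample_ids
    )
    fit <- xonet_fit(graph, subset_batch(batch, sample_ids[tr]), config,
                     seed = derive_seed(seed, paste0("site", s)), ...)
    test_b <- subset_batch(batch, sample_ids[test_idx])
    pr <- t(predict_probs(fit, test_b))
    colnames(pr) <- fit$classes
    est <- factor(fit$classes[max.col(pr)], levels = fit$classes)
    truth <- labels[test_idx]
    res[[s]] <- dplyr::bind_cols(
      tibble::tibble(site = s, n = length(test_idx)),
      metric_report(truth, est, pr)
    )
  }
  per_site <- dplyr::bind_rows(res)
  metric_cols <- setdiff(names(per_site), c("site", "n"))
  summary <- dplyr::bind_rows(
    dplyr::summarise(per_site, site = "mean",
                     dplyr::across(dplyr::all_of(metric_cols), mean)),
    dplyr::summarise(per_site, site = "worst",
                     dplyr::across(dplyr::all_of(metric_cols), min))
  )
  list(per_site = per_site, summary = summary)
}
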