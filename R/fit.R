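#' Fold-safe z-standardization
#'
#' Column means and population standard deviations are computed on the
#' training split only; the same affine transform is then applied verbatim
#' to validation/test data, so no test-set moments ever leak into
#' preprocessing. Constant columns transform to zero through the epsilon
#' guard.
#'
#' @param m Numeric samples x features training matrix.
#' @param eps Stability constant added to the standard deviation.
#' @return A `standardizer` object with `mu`, `sigma`, `eps`.
#' @export
fit_standardizer <- function(m, eps = 1e-8) {
  mu <- colMeans(m)
  sigma <- sqrt(pmax(colMeans(m^2) - mu^2, 0))
  structure(list(mu = mu, sigma = sigma, eps = eps), class = "standardizer")
}

#' @rdname fit_standardizer
#' @param stats A `standardizer`.
#' @export
apply_standardizer <- function(stats, m) {
  sweep(sweep(m, 2L, stats$mu, "-"), 2L, stats$sigma + stats$eps, "/")
}

#' Repeated stratified cross-validation plan
#'
#' Produces `r` independent stratified `k`-fold partitions of the cohort;
#' within each repeat the test folds partition the samples and every class
#' is spread across folds as evenly as possible (fold class counts differ
#' by at most one). The plan is deterministic given the seed and is meant
#' to be shared across all methods compared on the cohort.
#'
#' @param labels Factor (or coercible) of class labels.
#' @param sample_ids Character sample identifiers (defaults to names or
#'   indices of `labels`).
#' @param k Number of folds (default 5).
#' @param r Number of repeats (default 5).
#' @param seed Integer seed.
#' @return A `fold_plan` with an `assignments` tibble
#'   (`sample_id`, `repeat_id`, `fold`).
#' @export
make_fold_plan <- function(labels, sample_ids = NULL, k = 5L, r = 5L, seed = 1L) {
  labels <- as.factor(labels)
  n <- length(labels)
  sample_ids <- sample_ids %||% (names(labels) %||% as.character(seq_len(n)))
  stopifnot(length(sample_ids) == n, !anyDuplicated(sample_ids))
  rows <- purrr::map_dfr(seq_len(r), function(rep_i) {
    set.seed(derive_seed(seed, paste0("folds", rep_i)))
    fold <- integer(n)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
    tibble::tibble(sample_id = sample_ids, repeat_id = rep_i, fold = fold)
  })
  structure(list(assignments = rows, k = k, r = r, seed = seed),
            class = "fold_plan")
}

#' Stratified inner validation split
#'
#' Draws a class-stratified validation subset (default 10%) from the outer
#' training fold, for early stopping and threshold selection; the remainder
#' is used for fitting. Deterministic given the seed.
#'
#' @param ids Sample identifiers of the training fold.
#' @param labels Class labels aligned to `ids`.
#' @param frac Validation fraction (default 0.10).
#' @param seed Integer seed.
#' @return List with `fit_ids` and `val_ids`.
#' @export
split_inner_validation <- function(ids, labels, frac = 0.10, seed = 1L) {
  labels <- as.factor(labels)
  set.seed(derive_seed(seed, "innerval"))
  val <- character(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    n_val <- max(1L, round(frac * length(idx)))
    if (length(idx) <= 1L) next
    val <- c(val, ids[idx[sample.int(length(idx), n_val)]])
  }
  list(fit_ids = setdiff(ids, val), val_ids = val)
}

#' Assemble a patient batch aligned to the graph
#'
#' Binds the three standardized modality matrices to the graph's node
#' order and attaches the per-patient modality presence mask. Feature
#' columns must be named by node identifiers and cover every node of the
#' corresponding type.
#'
#' @param graph A `hetero_graph`.
#' @param expr Samples x genes matrix (columns named by `gene_id`).
#' @param cbeta Samples x CpG clusters matrix (columns named by
#'   `cluster_id`), e.g. from [summarize_cluster_methylation()] then
#'   standardization.
#' @param mirna Samples x miRNAs matrix (columns named by `mirna_id`).
#' @param labels Optional factor of subtype labels (levels define the class
#'   order).
#' @param sample_ids Optional sample identifiers (default: row names).
#' @return A `patient_batch`: list of node-aligned feature matrices `X`
#'   (nodes x patients per type), `mask` (3 x patients), integer labels `y`,
#'   `classes`, `sample_ids`.
#' @export
prepare_batch <- function(graph, expr, cbeta, mirna, labels = NULL,
                          sample_ids = NULL) {
  sample_ids <- sample_ids %||% rownames(expr) %||% as.character(seq_len(nrow(expr)))
  P <- length(sample_ids)
  stopifnot(nrow(expr) == P, nrow(cbeta) == P, nrow(mirna) == P)
  align <- function(m, ids, what) {
    missing <- setdiff(ids, colnames(m))
    if (length(missing) > 0L) {
      abort(sprintf("feature matrix is missing %d %s node column(s), e.g. %s",
                    length(missing), what, missing[1L]))
    }
    t(m[, ids, drop = FALSE])
  }
  X <- list(
    g = align(expr, graph$nodes$gene$gene_id, "gene"),
    c = align(cbeta, graph$nodes$cpg$cluster_id, "CpG cluster"),
    m = align(mirna, graph$nodes$mirna$mirna_id, "miRNA")
  )
  mask <- matrix(TRUE, 3L, P, dimnames = list(c("g", "c", "m"), NULL))
  y <- NULL
  classes <- NULL
  if (!is.null(labels)) {
    labels <- as.factor(labels)
    stopifnot(length(labels) == P)
    y <- as.integer(labels)
    classes <- levels(labels)
  }
  structure(
    list(X = X, mask = mask, y = y, classes = classes, sample_ids = sample_ids),
    class = "patient_batch"
  )
}

subset_batch <- function(batch, idx) {
  if (is.character(idx)) idx <- match(idx, batch$sample_ids)
  structure(
    list(
      X = purrr::map(batch$X, ~ .x[, idx, drop = FALSE]),
      mask = batch$mask[, idx, drop = FALSE],
      y = batch$y[idx], classes = batch$classes,
      sample_ids = batch$sample_ids[idx]
    ),
    class = "patient_batch"
  )
}

macro_f1_quick <- function(truth, est, K) {
  f1 <- vapply(seq_len(K), function(k) {
    tp <- sum(truth == k & est == k)
    fp <- sum(truth != k & est == k)
    fn <- sum(truth == k & est != k)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  mean(f1)
}

#' Fit the cross-omics graph network
#'
#' Minibatch Adam training with early stopping on inner-validation
#' Macro-F1. The inner validation split is drawn (stratified) from the
#' supplied batch unless explicit validation ids are given. When
#' `train_mask_prob > 0`, each epoch independently masks one entire
#' modality (chosen uniformly) with that probability before the forward
#' pass — the missingness-aware training variant.
#'
#' @param graph A `hetero_graph`.
#' @param batch A labelled `patient_batch` (training fold).
#' @param config A [xonet_config()].
#' @param val_ids Optional sample ids reserved for inner validation.
#' @param val_frac Inner validation fraction when `val_ids` is `NULL`.
#' @param lr Adam learning rate (default 1e-2).
#' @param max_epochs Maximum epochs (default 100).
#' @param patience Early-stopping patience in epochs (default 30).
#' @param batch_size Minibatch size (default 32; `NULL` trains full-batch).
#' @param train_mask_prob Per-minibatch probability of masking one modality.
#' @param monitor Inner-validation quantity for early stopping and
#'   checkpoint selection: `"nll"` (negative log-likelihood, default —
#'   continuous, so far less noisy on small validation splits) or
#'   `"macro_f1"`.
#' @param restarts Maximum number of training runs from fresh
#'   initializations (default 2). Minibatch training of this architecture
#'   occasionally lands in a poor optimum that is clearly visible as a high
#'   inner-validation loss; further restarts are skipped as soon as a run
#'   reaches `restart_nll`, and the run with the best monitored value wins.
#' @param restart_nll Inner-validation NLL below which a run is accepted
#'   without further restarts (default `0.3 * log(K)`).
#' @param seed Seed for the validation split, initialization and masking.
#' @param verbose Print progress.
#' @return A `xonet_fit`: best parameters, config, training history,
#'   validation ids, and the graph fingerprint the model is bound to.
#' @export
xonet_fit <- function(graph, batch, config = xonet_config(), val_ids = NULL,
                      val_frac = 0.10, lr = 1e-2, max_epochs = 100L,
                      patience = 30L, batch_size = 32L, train_mask_prob = 0,
                      monitor = c("nll", "macro_f1"), restarts = 2L,
                      restart_nll = NULL, seed = NULL,
                      verbose = FALSE) {
  monitor <- match.arg(monitor)
  stopifnot(inherits(batch, "patient_batch"), !is.null(batch$y))
  seed <- seed %||% config$seed
  config$seed <- seed
  K <- config$num_classes
  stopifnot(K == length(batch$classes))
  if (is.null(val_ids)) {
    sp <- split_inner_validation(batch$sample_ids, batch$classes[batch$y],
                                 frac = val_frac, seed = seed)
    val_ids <- sp$val_ids
  }
  fit_b <- subset_batch(batch, setdiff(batch$sample_ids, val_ids))
  val_b <- subset_batch(batch, val_ids)

  mp <- build_mp(graph, config)
  restart_nll <- restart_nll %||% (0.3 * log(K))
  overall <- NULL
  for (attempt in seq_len(max(1L, restarts))) {
  cfg_a <- config
  cfg_a$seed <- derive_seed(seed, paste0("attempt", attempt))
  params <- init_params(mp, cfg_a)
  state <- adam_init(params)
  set.seed(derive_seed(cfg_a$seed, "trainloop"))
  best <- list(score = -Inf, params = params, epoch = 0L)
  hist <- vector("list", max_epochs)
  stall <- 0L
  n_fit <- length(fit_b$sample_ids)
  bs <- min(batch_size %||% n_fit, n_fit)
  for (ep in seq_len(max_epochs)) {
    ord <- sample.int(n_fit)
    starts <- seq(1L, n_fit, by = bs)
    ep_loss <- 0
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + bs - 1L, n_fit)]
      b <- if (length(idx) == n_fit) fit_b else subset_batch(fit_b, idx)
      if (train_mask_prob > 0 && runif(1) < train_mask_prob) {
        b <- apply_missingness(b, sample(c("g", "c", "m"), 1L))
      }
      lg <- xonet_loss_grad(params, mp, config, graph, b, b$y, training = TRUE)
      if (!is.finite(lg$loss)) {
        abort(sprintf("non-finite loss at epoch %d (lr %.3g); training aborted",
                      ep, lr))
      }
      ep_loss <- ep_loss + lg$loss * length(idx) / n_fit
      st <- adam_step(params, lg$grads, state, lr = lr)
      params <- st$params
      state <- st$state
    }
    lg <- list(loss = ep_loss)
    val_probs <- forward_probs_cpp(params, mp, val_b, config)
    est <- max.col(t(val_probs))
    val_f1 <- macro_f1_quick(val_b$y, est, K)
    val_nll <- -mean(log(pmax(val_probs[cbind(val_b$y, seq_along(val_b$y))],
                              1e-300)))
    score <- if (monitor == "nll") -val_nll else val_f1
    hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = lg$loss,
                                 val_macro_f1 = val_f1, val_nll = val_nll)
    if (score > best$score + 1e-9) {
      best <- list(score = score, params = params, epoch = ep,
                   val_macro_f1 = val_f1)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
    if (verbose && ep %% 10L == 0L) {
      message(sprintf("epoch %3d loss %.4f val monitor %.3f", ep, lg$loss, score))
    }
  }
  best$history <- dplyr::bind_rows(hist)
  best$attempt <- attempt
  if (is.null(overall) || best$score > overall$score) overall <- best
  best_nll <- min(best$history$val_nll)
  if (best_nll <= restart_nll) break
  }
  best <- overall
  structure(
    list(
      params = best$params, config = config, mp = mp,
      classes = batch$classes,
      history = best$history, best_epoch = best$epoch,
      best_val_macro_f1 = best$val_macro_f1 %||% NA_real_,
      monitor = monitor, attempts = best$attempt, val_ids = val_ids,
      train_mask_prob = train_mask_prob,
      graph_fingerprint = graph_fingerprint(graph)
    ),
    class = "xonet_fit"
  )
}

#' @export
print.xonet_fit <- function(x, ...) {
  cat(sprintf(
    "<xonet_fit> %d classes, hidden %d, %d layers; best epoch %d (val macro-F1 %.3f)\n",
    length(x$classes), x$config$hidden_dim, x$config$num_layers,
    x$best_epoch, x$best_val_macro_f1
  ))
  invisible(x)
}

# K x P probability matrix for a batch. The compiled forward handles the
# standard unit-gate path; gated predictions go through the R path.
predict_probs <- function(fit, batch, gates = NULL) {
  if (is.null(gates)) {
    return(forward_probs_cpp(fit$params, fit$mp, batch, fit$config))
  }
  fw <- xonet_forward(fit$params, fit$mp, batch, fit$config, gates = gates)
  fw$probs
}

#' Predict subtype probabilities or classes
#'
#' @param object A `xonet_fit`.
#' @param batch A `patient_batch` aligned to the same graph.
#' @param type `"prob"` (tibble of per-class probabilities), `"class"`
#'   (factor of predicted classes) or `"both"`.
#' @param ... Unused.
#' @return Tibble with `sample_id`, predicted class, and one probability
#'   column per class (`type = "prob"`/`"both"`), or a factor.
#' @export
predict.xonet_fit <- function(object, batch, type = c("prob", "class", "both"), ...) {
  type <- match.arg(type)
  pr <- predict_probs(object, batch)
  est <- factor(object$classes[max.col(t(pr))], levels = object$classes)
  if (type == "class") return(est)
  out <- tibble::as_tibble(t(pr), .name_repair = "minimal")
  names(out) <- paste0(".pred_", object$classes)
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = batch$sample_ids, .pred_class = est), out
  )
  out
}

#' Save / load a model checkpoint bound to its graph
#'
#' The checkpoint stores parameters, configuration and the graph
#' fingerprint; loading verifies the fingerprint against the supplied graph
#' and refuses a mismatch.
#'
#' @param fit A `xonet_fit`.
#' @param path Destination file.
#' @param graph The graph the checkpoint must match.
#' @return `path` (saver) or the restored `xonet_fit` (loader).
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, graph) {
  fit <- readRDS(path)
  if (!identical(fit$graph_fingerprint, graph_fingerprint(graph))) {
    abort("checkpoint was trained on a different graph (fingerprint mismatch)")
  }
  fit
}

#' Repeated cross-validated training with out-of-fold predictions
#'
#' Runs the full fold-safe protocol: for every (repeat, fold) of the plan,
#' modality standardizers are fitted on the training fold only, an inner
#' validation split is drawn from the training fold for early stopping,
#' the model is trained, and the held-out test fold is predicted. Every
#' sample therefore receives one out-of-fold prediction per repeat.
#'
#' @param graph A `hetero_graph`.
#' @param expr,probe_beta,mirna Raw samples x features matrices (probe-level
#'   betas are summarized to clusters internally).
#' @param labels Factor of subtype labels.
#' @param config A [xonet_config()].
#' @param fold_plan Optional pre-built [make_fold_plan()]; otherwise built
#'   from `k`, `r`, `seed`.
#' @param k,r,seed Fold plan parameters.
#' @param keep_fits Keep the per-fold fitted models (needed for
#'   attribution aggregation); off by default to save memory.
#' @param ... Passed to [xonet_fit()] (e.g. `lr`, `max_epochs`, `patience`,
#'   `train_mask_prob`).
#' @return A `xonet_cv` object: `oof` tibble (sample, repeat, fold, label,
#'   predicted class and probabilities), per-fold metric tibble, the fold
#'   plan, and optionally the fits.
#' @export
xonet_cv <- function(graph, expr, probe_beta, mirna, labels,
                     config = xonet_config(), fold_plan = NULL,
                     k = 5L, r = 5L, seed = 1L, keep_fits = FALSE, ...) {
  labels <- as.factor(labels)
  sample_ids <- rownames(expr) %||% as.character(seq_along(labels))
  fold_plan <- fold_plan %||% make_fold_plan(labels, sample_ids, k, r, seed)
  clusters <- graph$nodes$cpg
  cbeta_raw <- summarize_cluster_methylation(probe_beta, clusters)
  oof <- list()
  fits <- list()
  fold_keys <- dplyr::distinct(fold_plan$assignments, .data$repeat_id, .data$fold)
  for (i in seq_len(nrow(fold_keys))) {
    rep_i <- fold_keys$repeat_id[i]
    fold_i <- fold_keys$fold[i]
    assign_r <- dplyr::filter(fold_plan$assignments, .data$repeat_id == rep_i)
    test_ids <- assign_r$sample_id[assign_r$fold == fold_i]
    train_ids <- setdiff(sample_ids, test_ids)
    tr <- match(train_ids, sample_ids)
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
    fit <- xonet_fit(graph, subset_batch(batch, train_ids), config,
                     seed = derive_seed(seed, sprintf("fit%d_%d", rep_i, fold_i)),
                     ...)
    test_b <- subset_batch(batch, test_ids)
    pr <- predict(fit, test_b, type = "both")
    oof[[i]] <- dplyr::bind_cols(
      tibble::tibble(repeat_id = rep_i, fold = fold_i,
                     label = labels[match(test_ids, sample_ids)]),
      pr
    )
    if (keep_fits) {
      fit$standardizers <- std
      fits[[i]] <- fit
    }
  }
  oof <- dplyr::bind_rows(oof)
  fold_metrics <- oof |>
    dplyr::group_by(.data$repeat_id, .data$fold) |>
    dplyr::summarise(
      accuracy = mean(.data$.pred_class == .data$label),
      macro_f1 = macro_f1_quick(as.integer(.data$label),
                                as.integer(.data$.pred_class),
                                length(levels(.data$label))),
      .groups = "drop"
    )
  structure(
    list(oof = oof, fold_metrics = fold_metrics, fold_plan = fold_plan,
         fits = if (keep_fits) fits else NULL, classes = levels(labels)),
    class = "xonet_cv"
  )
}

#' @export
print.xonet_cv <- function(x, ...) {
  cat(sprintf(
    "<xonet_cv> %d repeats x %d folds; OOF accuracy %.3f\n",
    x$fold_plan$r, x$fold_plan$k, mean(x$oof$.pred_class == x$oof$label)
  ))
  invisible(x)
}
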