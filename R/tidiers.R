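# broom-style accessors for fitted objects and CV runs.

#' Tidy the training history of a fitted model
#'
#' @param x A `xonet_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `train_loss`,
#'   `val_macro_f1`.
#' @export
tidy.xonet_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted model
#'
#' @param x A `xonet_fit`.
#' @param ... Unused.
#' @return One-row tibble: epochs run, best epoch, best validation
#'   Macro-F1, final training loss, parameter count.
#' @export
glance.xonet_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_macro_f1 = x$best_val_macro_f1,
    final_train_loss = x$history$train_loss[nrow(x$history)],
    n_parameters = sum(vapply(x$params, length, 0L)),
    hidden_dim = x$config$hidden_dim,
    num_layers = x$config$num_layers
  )
}

#' Per-fold metrics of a cross-validation run
#'
#' @param x A `xonet_cv`.
#' @param ... Unused.
#' @return Tibble with one row per (repeat, fold).
#' @export
tidy.xonet_cv <- function(x, ...) {
  x$fold_metrics
}

#' One-row out-of-fold summary of a cross-validation run
#'
#' @param x A `xonet_cv`.
#' @param ... Unused.
#' @return One-row tibble of OOF discrimination metrics.
#' @export
glance.xonet_cv <- function(x, ...) {
  metric_report(x$oof$label, x$oof$.pred_class, x$oof)
}
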