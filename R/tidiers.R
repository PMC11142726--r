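#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted edge classifier
#'
#' @param x A `"grn_fit"`.
#' @param ... Unused.
#' @return The training trace: one row per epoch with `epoch`, `lr`, `loss`.
#' @method tidy grn_fit
#' @export
tidy.grn_fit <- function(x, ...) {
  x$loss_trace
}

#' @rdname tidy.grn_fit
#' @return `glance()` returns a one-row model summary.
#' @method glance grn_fit
#' @export
glance.grn_fit <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  tibble::tibble(
    n_genes = length(x$gene_ids),
    n_train = x$n_train,
    epochs = nrow(x$loss_trace),
    final_loss = if (nrow(x$loss_trace) > 0) {
      x$loss_trace$loss[nrow(x$loss_trace)]
    } else {
      NA_real_
    },
    n_parameters = n_par,
    aggregator = x$config$aggregator,
    embed_dim = x$config$embed_dim,
    k_pool = x$config$k_pool,
    cnn_layers = x$config$cnn_layers
  )
}

#' Tidy cross-validation results
#'
#' @param x A `"grn_cv"`.
#' @param ... Unused.
#' @return One row of metrics per fold (confusion counts, FPR/TPR, precision,
#'   recall, AUROC, AUPRC).
#' @method tidy grn_cv
#' @export
tidy.grn_cv <- function(x, ...) {
  x$metrics
}

#' @rdname tidy.grn_cv
#' @return `glance()` returns the one-row across-fold means.
#' @method glance grn_cv
#' @export
glance.grn_cv <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(n_folds = nrow(x$metrics)), x$summary)
}

#' Plot the training loss trace
#'
#' @param object A `"grn_fit"`.
#' @param ... Unused.
#' @return A ggplot of mean training loss per epoch.
#' @method autoplot grn_fit
#' @export
autoplot.grn_fit <- function(object, ...) {
  ggplot2::ggplot(object$loss_trace,
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "epoch", y = "mean training BCE loss",
                  title = "Training loss") +
    ggplot2::theme_minimal()
}

#' Plot per-fold ranking metrics
#'
#' @param object A `"grn_cv"`.
#' @param ... Unused.
#' @return A ggplot showing AUROC and AUPRC per fold with the cross-fold
#'   mean.
#' @method autoplot grn_cv
#' @export
autoplot.grn_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object$metrics, "fold", "auroc", "auprc"),
    c("auroc", "auprc"), names_to = "metric", values_to = "value")
  means <- dplyr::summarise(dplyr::group_by(long, .data$metric),
                            value = mean(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::geom_point(data = means, color = "firebrick", size = 3,
                        shape = 18) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "area under curve",
                  title = "Cross-validated ranking performance",
                  subtitle = "points: folds; diamond: mean") +
    ggplot2::theme_minimal()
}
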