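#' Run configuration for link-prediction models
#'
#' Collects every tunable of the pipeline: embedding geometry, aggregator
#' choice, Top-k pooling, the convolutional head, the optimisation schedule
#' and the cross-validation protocol. Defaults follow the published model:
#' 256-dimensional embeddings from one hop of MEAN aggregation, Top-k pooling
#' with k = 1, a stacked 3-layer CNN with 2x2 kernels, and a learning rate of
#' 0.01 decayed to 80% every 10 epochs.
#'
#' @param embed_dim Output embedding dimension d (default 256).
#' @param hops Number of neighborhood-aggregation layers l, 1-3 (default 1).
#' @param aggregator Neighbor aggregation: `"mean"`, `"max"` or `"lstm"`.
#' @param k_pool Number of globally influential nodes kept by Top-k pooling.
#' @param use_topk Keep the Top-k pooling branch? `k_pool = 0` forces `FALSE`.
#' @param cnn_layers Number of stacked feature-extraction blocks, 1 or 3.
#' @param kernel_size Convolution kernel side (default 2).
#' @param fc_hidden Width of the first fully connected layer (default 256).
#' @param lr0,lr_decay,lr_interval Step-decay learning-rate schedule:
#'   `lr0 * lr_decay^(epoch %/% lr_interval)`.
#' @param epochs,batch_size Training length and minibatch size.
#' @param n_folds Cross-validation folds (default 5).
#' @param neg_ratio Negatives sampled per positive edge (default 1).
#' @param threshold Score threshold for confusion counts (default 0.5).
#' @param clip_norm Global L2 norm ceiling for each minibatch gradient
#'   (`Inf` disables clipping).
#' @param seed Master seed; every random substream derives from it.
#' @param log_transform,standardize Node-feature preparation flags (log1p,
#'   then per-gene standardization).
#' @param directed_neighbors If `TRUE`, a gene aggregates only its incoming
#'   regulators; default is the undirected (symmetrized) neighborhood.
#' @param keep_self_loops Retain self-loops when reading reference networks.
#' @param gate_topk If `TRUE` (default) the pooled rows fed to the pair matrix
#'   are gated by `tanh` of the projection score; `FALSE` uses raw embeddings.
#' @return A validated list of class `"grn_config"`.
#' @export
#' @examples
#' cfg <- grn_config(epochs = 5, seed = 42)
#' cfg$embed_dim
grn_config <- function(embed_dim = 256L, hops = 1L,
                       aggregator = c("mean", "max", "lstm"),
                       k_pool = 1L, use_topk = TRUE,
                       cnn_layers = 3L, kernel_size = 2L, fc_hidden = 256L,
                       lr0 = 0.01, lr_decay = 0.8, lr_interval = 10L,
                       epochs = 100L, batch_size = 256L,
                       n_folds = 5L, neg_ratio = 1, threshold = 0.5,
                       clip_norm = Inf, seed = 1L,
                       log_transform = TRUE, standardize = TRUE,
                       directed_neighbors = FALSE, keep_self_loops = FALSE,
                       gate_topk = TRUE) {
  aggregator <- match.arg(aggregator)
  embed_dim <- as.integer(embed_dim)
  stopifnot(embed_dim >= 1, hops %in% 1:3, k_pool >= 0,
            kernel_size >= 1, fc_hidden >= 1,
            lr0 > 0, lr_decay > 0, lr_decay <= 1, lr_interval >= 1,
            epochs >= 0, batch_size >= 1, n_folds >= 2,
            neg_ratio > 0, threshold > 0, threshold < 1)
  if (!cnn_layers %in% c(1L, 3L)) {
    stop("`cnn_layers` must be 1 or 3, got ", cnn_layers)
  }
  if (k_pool == 0L) use_topk <- FALSE
  if (!use_topk) k_pool <- 0L
  cfg <- list(
    embed_dim = embed_dim, hops = as.integer(hops), aggregator = aggregator,
    k_pool = as.integer(k_pool), use_topk = isTRUE(use_topk),
    cnn_layers = as.integer(cnn_layers), kernel_size = as.integer(kernel_size),
    fc_hidden = as.integer(fc_hidden),
    lr0 = lr0, lr_decay = lr_decay, lr_interval = as.integer(lr_interval),
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    n_folds = as.integer(n_folds), neg_ratio = neg_ratio,
    threshold = threshold, clip_norm = clip_norm, seed = as.integer(seed),
    log_transform = isTRUE(log_transform), standardize = isTRUE(standardize),
    directed_neighbors = isTRUE(directed_neighbors),
    keep_self_loops = isTRUE(keep_self_loops),
    gate_topk = isTRUE(gate_topk)
  )
  structure(cfg, class = "grn_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [grn_config()]; unknown keys are an error so
#' that typos never silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @param ... Overrides applied after the file is read (e.g. from CLI flags).
#' @return A `"grn_config"` object.
#' @export
read_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(grn_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  do.call(grn_config, vals)
}

#' @export
print.grn_config <- function(x, ...) {
  cat("<grn_config>\n")
  cat(sprintf("  embedding: d=%d, %d hop(s), %s aggregator\n",
              x$embed_dim, x$hops, x$aggregator))
  cat(sprintf("  top-k pooling: %s (k=%d, %s rows)\n",
              if (x$use_topk) "on" else "off", x$k_pool,
              if (x$gate_topk) "gated" else "raw"))
  cat(sprintf("  head: %d-layer CNN, kernel %d, fc %d\n",
              x$cnn_layers, x$kernel_size, x$fc_hidden))
  cat(sprintf("  training: %d epochs, batch %d, lr %g x%g every %d\n",
              x$epochs, x$batch_size, x$lr0, x$lr_decay, x$lr_interval))
  cat(sprintf("  protocol: %d folds, neg_ratio %g, threshold %g, seed %d\n",
              x$n_folds, x$neg_ratio, x$threshold, x$seed))
  invisible(x)
}
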