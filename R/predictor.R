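#' Learning rate at a given epoch
#'
#' Step-decay schedule: the initial rate is multiplied by `decay` once every
#' `interval` epochs, i.e. `lr0 * decay^(epoch %/% interval)` with `epoch`
#' counted from 0. The defaults give 0.01, 0.008 at epoch 10, 0.0064 at
#' epoch 20, and so on.
#'
#' @param epoch Zero-based epoch counter.
#' @param lr0 Initial learning rate.
#' @param decay Multiplicative decay factor in (0, 1].
#' @param interval Epochs between decays (>= 1).
#' @return The learning rate, a positive scalar.
#' @export
lr_at_epoch <- function(epoch, lr0 = 0.01, decay = 0.8, interval = 10L) {
  stopifnot(epoch >= 0, interval >= 1)
  lr0 * decay^(epoch %/% interval)
}

#' Binary cross-entropy loss
#'
#' Mean binary cross-entropy over a batch, with predictions clamped to
#' `[eps, 1 - eps]` before the logarithm.
#'
#' @param predictions Predicted probabilities in `[0, 1]`.
#' @param labels True labels in `{0, 1}`.
#' @param eps Clamping constant (default `1e-7`).
#' @return A non-negative scalar.
#' @export
#' @examples
#' bce_loss(c(0.5, 0.5), c(1, 0))  # log(2)
bce_loss <- function(predictions, labels, eps = 1e-7) {
  if (length(predictions) != length(labels)) {
    stop("predictions and labels differ in length: ",
         length(predictions), " vs ", length(labels))
  }
  p <- clamp(predictions, eps, 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Score pre-assembled pair matrices with a model's convolutional head
#'
#' Runs the stacked CNN + fully connected head of a fitted (or freshly
#' initialized) model over a batch of `(k + 2) x d` pair matrices in
#' evaluation mode (frozen normalization statistics), returning one
#' probability per matrix.
#'
#' @param E_batch List of `(k + 2) x d` pair feature matrices sharing one
#'   shape.
#' @param fit A `"grn_fit"` object.
#' @return Numeric vector of probabilities in `[0, 1]`, one per matrix.
#' @export
score_pairs <- function(E_batch, fit) {
  stopifnot(inherits(fit, "grn_fit"), length(E_batch) > 0)
  shp <- dim(E_batch[[1]])
  ok <- vapply(E_batch, function(e) identical(dim(e), shp), logical(1))
  if (!all(ok)) stop("all pair matrices in a batch must share one shape")
  B <- length(E_batch)
  E <- array(0, c(B, shp[1], shp[2], 1L))
  for (b in seq_len(B)) E[b, , , 1] <- E_batch[[b]]
  head_forward_eval(fit$params, fit$state, E, fit$config)
}

# Evaluation-mode pass through the CNN head alone (input already assembled).
head_forward_eval <- function(params, state, E, config) {
  B <- dim(E)[1]
  geo <- state$geo
  x <- E
  segs <- vector("list", length(geo$blocks))
  for (b in seq_along(geo$blocks)) {
    g <- geo$blocks[[b]]
    bn <- nn_bn_forward(x, params[[paste0("cnn", b, ".bn.gamma")]],
                        params[[paste0("cnn", b, ".bn.beta")]],
                        state$bn_mean[[b]], state$bn_var[[b]], "eval")
    cz <- nn_conv_forward(bn$out, params[[paste0("cnn", b, ".conv.K")]],
                          params[[paste0("cnn", b, ".conv.b")]])
    pl <- nn_pool_forward(pmax(cz, 0), g$ph, g$pw)
    segs[[b]] <- matrix(pl$out, nrow = B)
    x <- pl$out
  }
  feat <- do.call(cbind, segs)
  if (is.null(params[["fc1.W"]])) {
    params[["fc1.W"]] <- glorot(ncol(feat), config$fc_hidden,
                                derive_seed(state$seed, "fc1"),
                                dims = c(ncol(feat), config$fc_hidden))
    params[["fc1.b"]] <- numeric(config$fc_hidden)
  }
  h1 <- pmax(sweep(feat %*% params[["fc1.W"]], 2, params[["fc1.b"]], "+"), 0)
  drop(sigmoid(drop(h1 %*% params[["fc2.W"]]) + params[["fc2.b"]]))
}

map_pairs <- function(pairs, gene_ids) {
  pi <- match(pairs$tf, gene_ids)
  pj <- match(pairs$target, gene_ids)
  bad <- unique(c(pairs$tf[is.na(pi)], pairs$target[is.na(pj)]))
  if (length(bad) > 0) {
    stop("gene id(s) unknown to the model: ", paste(bad, collapse = ", "))
  }
  list(i = pi, j = pj)
}

#' Fit the edge classifier
#'
#' Trains the full model — GraphSAGE layer(s), the Top-k pooling projection
#' and the convolutional scoring head — end to end by minibatch Adam on
#' binary cross-entropy, with the step-decay learning-rate schedule of
#' [lr_at_epoch()]. The run is fully reproducible from `config$seed`.
#'
#' @param labeled Data frame of training edges: columns `tf`, `target`,
#'   `label` (both classes must be present).
#' @param graph A `"gene_graph"` built from the *training* positive edges
#'   only (see [build_gene_graph()]); using test edges here leaks labels.
#' @param config A [grn_config()].
#' @return An object of class `"grn_fit"` holding parameters, frozen
#'   normalization statistics, the config, the graph, and the per-epoch loss
#'   trace (see `tidy()` / `glance()` / `autoplot()` methods).
#' @export
grn_fit <- function(labeled, graph, config = grn_config()) {
  stopifnot(inherits(graph, "gene_graph"))
  if (length(unique(labeled$label)) < 2) {
    stop("training set must contain both positive and negative edges")
  }
  idx <- map_pairs(labeled, graph$gene_ids)
  y <- as.numeric(labeled$label)
  n <- length(y)
  init <- grn_init_params(ncol(graph$features), config,
                          derive_seed(config$seed, "init"))
  params <- init$params
  state <- init$state
  opt <- adam_init()
  trace <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at_epoch(epoch - 1L, config$lr0, config$lr_decay,
                      config$lr_interval)
    perm <- with_seed(derive_seed(config$seed, "shuffle", epoch),
                      sample.int(n))
    starts <- seq(1, n, by = config$batch_size)
    batch_losses <- numeric(length(starts))
    batch_sizes <- integer(length(starts))
    for (s in seq_along(starts)) {
      take <- perm[starts[s]:min(starts[s] + config$batch_size - 1L, n)]
      lg <- grn_loss_grads(params, state, graph,
                           idx$i[take], idx$j[take], y[take], config,
                           mode = "train",
                           lstm_seed = derive_seed(config$seed, "perm",
                                                   epoch * 1000L + s))
      params <- lg$params
      state <- lg$state
      grads <- clip_global_norm(lg$grads, config$clip_norm)
      step <- adam_step(opt, params, grads, lr)
      opt <- step$opt
      params <- step$params
      batch_losses[s] <- lg$loss
      batch_sizes[s] <- length(take)
    }
    trace[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr,
      loss = sum(batch_losses * batch_sizes) / sum(batch_sizes))
  }
  if (config$epochs == 0) {
    # materialize the lazy fully connected layer so prediction works
    fw <- grn_forward(params, state, graph, idx$i[1], idx$j[1], config,
                      mode = "eval",
                      lstm_seed = derive_seed(config$seed, "perm-eval"))
    params <- fw$params
  }
  structure(list(params = params, state = state, config = config,
                 graph = graph, gene_ids = graph$gene_ids,
                 loss_trace = dplyr::bind_rows(trace),
                 n_train = n),
            class = "grn_fit")
}

#' @export
print.grn_fit <- function(x, ...) {
  cat(sprintf("<grn_fit> %d genes, %d training edges, %d epoch(s)\n",
              length(x$gene_ids), x$n_train, nrow(x$loss_trace)))
  if (nrow(x$loss_trace) > 0) {
    cat(sprintf("  final training loss: %.4f\n",
                x$loss_trace$loss[nrow(x$loss_trace)]))
  }
  invisible(x)
}

#' Score candidate regulatory edges with a fitted model
#'
#' Computes embeddings from the model's training graph, assembles the pair
#' matrix for every candidate (TF, target) pair and scores it with the
#' convolutional head in evaluation mode. Output order matches input order
#' and repeated calls are identical.
#'
#' @param fit A `"grn_fit"`.
#' @param pairs Data frame with columns `tf` and `target` (gene ids known to
#'   the model).
#' @return A tibble `tf, target, score` with scores in `[0, 1]`.
#' @export
predict_edges <- function(fit, pairs) {
  stopifnot(inherits(fit, "grn_fit"))
  idx <- map_pairs(pairs, fit$gene_ids)
  fw <- grn_forward(fit$params, fit$state, fit$graph, idx$i, idx$j,
                    fit$config, mode = "eval",
                    lstm_seed = derive_seed(fit$config$seed, "perm-eval"))
  tibble::tibble(tf = pairs$tf, target = pairs$target,
                 score = as.numeric(fw$yhat))
}

#' @export
predict.grn_fit <- function(object, pairs, ...) {
  predict_edges(object, pairs)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single serialized archive containing every parameter
#' tensor, the frozen normalization statistics, the configuration and the
#' training graph; `read_checkpoint(write_checkpoint(fit, f))` reproduces the
#' object bit for bit.
#'
#' @param fit A `"grn_fit"`.
#' @param path File path for the checkpoint.
#' @return `write_checkpoint()` returns `path` invisibly;
#'   `read_checkpoint()` returns the restored `"grn_fit"`.
#' @export
write_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "grn_fit"))
  saveRDS(fit, path, version = 3)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "grn_fit")) stop("not a grnlink checkpoint: ", path)
  fit
}
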