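# GraphSAGE-style neighborhood aggregation and Top-k pooling.
#
# Each hop updates node v as h_v <- ReLU(W %*% c(h_v, agg({h_u: u in N(v)})))
# with agg = elementwise mean, elementwise max, or the final hidden state of
# an LSTM run over a seeded random permutation of the neighbors. A node with
# no neighbors aggregates to the zero vector. Internal *_fwd functions carry
# the caches the backward pass needs.

lstm_init <- function(d_in, seed) {
  list(Wx = glorot(d_in, 4 * d_in, derive_seed(seed, "lstm.Wx"),
                   dims = c(d_in, 4 * d_in)),
       Wh = glorot(d_in, 4 * d_in, derive_seed(seed, "lstm.Wh"),
                   dims = c(d_in, 4 * d_in)),
       b = numeric(4 * d_in))
}

agg_forward <- function(feats, graph, aggregator, lstm_params = NULL,
                        perm_seed = 0L) {
  n <- graph$n_nodes
  d <- ncol(feats)
  A <- matrix(0, n, d)
  cache <- list(aggregator = aggregator)
  if (aggregator == "mean") {
    M <- matrix(0, n, n)
    for (v in seq_len(n)) {
      nb <- graph$neighbors[[v]]
      if (length(nb) > 0) M[v, nb] <- 1 / length(nb)
    }
    A <- M %*% feats
    cache$M <- M
  } else if (aggregator == "max") {
    idxmat <- matrix(0L, n, d)
    for (v in seq_len(n)) {
      nb <- graph$neighbors[[v]]
      if (length(nb) == 0) next
      sub <- feats[nb, , drop = FALSE]
      j <- max.col(t(sub), ties.method = "first")
      A[v, ] <- sub[cbind(j, seq_len(d))]
      idxmat[v, ] <- nb[j]
    }
    cache$idxmat <- idxmat
  } else if (aggregator == "lstm") {
    if (is.null(lstm_params)) stop("lstm aggregator requires lstm parameters")
    perms <- vector("list", n)
    caches <- vector("list", n)
    with_seed(perm_seed, {
      for (v in seq_len(n)) {
        nb <- graph$neighbors[[v]]
        if (length(nb) == 0) next
        perms[[v]] <- nb[sample.int(length(nb))]
        fw <- nn_lstm_forward(feats[perms[[v]], , drop = FALSE],
                              lstm_params$Wx, lstm_params$Wh, lstm_params$b)
        A[v, ] <- fw$h
        caches[[v]] <- fw$cache
      }
    })
    cache$perms <- perms
    cache$caches <- caches
  } else {
    stop("unknown aggregator: ", aggregator)
  }
  list(A = A, cache = cache)
}

agg_backward <- function(dA, cache, graph, feats, lstm_params = NULL) {
  n <- nrow(dA)
  d <- ncol(dA)
  dfeats <- matrix(0, nrow(feats), ncol(feats))
  out <- list()
  if (cache$aggregator == "mean") {
    dfeats <- crossprod(cache$M, dA)
  } else if (cache$aggregator == "max") {
    idx <- as.vector(cache$idxmat)
    keep <- idx > 0L
    lin <- idx + (rep(seq_len(d), each = n) - 1L) * nrow(feats)
    if (any(keep)) {
      s <- rowsum(as.vector(dA)[keep], lin[keep])
      dfeats[as.integer(rownames(s))] <- dfeats[as.integer(rownames(s))] + s
    }
  } else if (cache$aggregator == "lstm") {
    dWx <- lstm_params$Wx * 0
    dWh <- lstm_params$Wh * 0
    db <- lstm_params$b * 0
    for (v in seq_len(n)) {
      if (is.null(cache$caches[[v]])) next
      bk <- nn_lstm_backward(dA[v, ], cache$caches[[v]],
                             lstm_params$Wx, lstm_params$Wh)
      dfeats[cache$perms[[v]], ] <- dfeats[cache$perms[[v]], , drop = FALSE] +
        bk$dxs
      dWx <- dWx + bk$dWx
      dWh <- dWh + bk$dWh
      db <- db + bk$db
    }
    out$dWx <- dWx
    out$dWh <- dWh
    out$db <- db
  }
  out$dfeats <- dfeats
  out
}

#' Aggregate neighbor features
#'
#' One neighborhood-aggregation step: row `v` of the result is the mean, the
#' elementwise max, or the final LSTM state (over a seeded random neighbor
#' ordering) of the feature rows of `N(v)`. Empty neighborhoods aggregate to
#' the zero vector.
#'
#' @param feats Node-by-feature numeric matrix.
#' @param graph A `"gene_graph"`.
#' @param aggregator `"mean"`, `"max"` or `"lstm"`.
#' @param lstm_params LSTM parameters (required for `"lstm"`); see
#'   the internal initializer used by [grn_fit()].
#' @param perm_seed Seed for the LSTM neighbor permutation.
#' @return A matrix of the same shape as `feats`.
#' @export
aggregate_neighbors <- function(feats, graph,
                                aggregator = c("mean", "max", "lstm"),
                                lstm_params = NULL, perm_seed = 0L) {
  aggregator <- match.arg(aggregator)
  agg_forward(feats, graph, aggregator, lstm_params, perm_seed)$A
}

sage_layer_fwd <- function(feats, graph, W, aggregator,
                           lstm_params = NULL, perm_seed = 0L) {
  ag <- agg_forward(feats, graph, aggregator, lstm_params, perm_seed)
  Z <- cbind(feats, ag$A) %*% W
  list(H = pmax(Z, 0),
       cache = list(feats = feats, A = ag$A, Z = Z, agg = ag$cache))
}

#' Apply one GraphSAGE layer
#'
#' Updates every node as `ReLU(W %*% c(h_v, aggregate(N(v))))` — the
#' concatenate-then-project update with a ReLU nonlinearity and no row
#' normalization.
#'
#' @inheritParams aggregate_neighbors
#' @param W Weight matrix of shape `(2 * ncol(feats)) x d_out`.
#' @return Node-by-`d_out` matrix of updated embeddings.
#' @export
sage_layer <- function(feats, graph, W, aggregator = c("mean", "max", "lstm"),
                       lstm_params = NULL, perm_seed = 0L) {
  aggregator <- match.arg(aggregator)
  if (nrow(W) != 2 * ncol(feats)) {
    stop(sprintf("W has %d rows but concat(self, neighbors) has width %d",
                 nrow(W), 2 * ncol(feats)))
  }
  sage_layer_fwd(feats, graph, W, aggregator, lstm_params, perm_seed)$H
}

#' Embed all genes with stacked GraphSAGE layers
#'
#' Applies one [sage_layer()] per hop; with `l` layers each embedding is a
#' function of the l-hop neighborhood only.
#'
#' @inheritParams aggregate_neighbors
#' @param layer_params List with one element per hop, each containing `W` and,
#'   for the LSTM aggregator, `lstm`.
#' @return The n-by-d node embedding matrix (non-negative after the final
#'   ReLU).
#' @export
embed_genes <- function(feats, graph, layer_params,
                        aggregator = c("mean", "max", "lstm"),
                        perm_seed = 0L) {
  aggregator <- match.arg(aggregator)
  if (length(layer_params) == 0) stop("layer_params must not be empty")
  H <- feats
  for (t in seq_along(layer_params)) {
    H <- sage_layer(H, graph, layer_params[[t]]$W, aggregator,
                    layer_params[[t]]$lstm,
                    perm_seed = perm_seed + t)
  }
  H
}

#' Select the k most globally influential genes by Top-k pooling
#'
#' Scores every node by the ReLU of its embedding projected onto the unit
#' vector `p / ||p||`, keeps the `k` highest-scoring nodes (ties broken by
#' lowest node index), and gates the selected rows by `tanh` of their score so
#' the selection stays differentiable.
#'
#' @param X n-by-d node embedding matrix.
#' @param p Learnable projection d-vector (must be nonzero).
#' @param k Number of nodes to keep, `1 <= k <= n`.
#' @param adjacency Optional n-by-n adjacency matrix; if given, its
#'   restriction to the selected nodes is returned as `pruned_adjacency`.
#' @return A list: `scores` (length n), `selected` (k node indices in
#'   descending-score order), `gated` (k-by-d gated embedding rows), and
#'   `pruned_adjacency` (or `NULL`).
#' @export
#' @examples
#' X <- rbind(c(1, 0), c(0, 2), c(3, 0))
#' topk_pool(X, p = c(1, 0), k = 1)$gated  # 3 * tanh(3), 0
topk_pool <- function(X, p, k, adjacency = NULL) {
  n <- nrow(X)
  if (k < 1 || k > n) stop("k must lie in [1, n]; got k=", k, ", n=", n)
  nrm <- sqrt(sum(p^2))
  if (nrm == 0) stop("projection vector p must be nonzero")
  scores <- pmax(drop(X %*% (p / nrm)), 0)
  ord <- order(-scores, seq_along(scores))
  selected <- ord[seq_len(k)]
  gated <- X[selected, , drop = FALSE] * tanh(scores[selected])
  pruned <- if (!is.null(adjacency)) {
    adjacency[selected, selected, drop = FALSE]
  }
  list(scores = scores, selected = selected, gated = gated,
       pruned_adjacency = pruned)
}
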