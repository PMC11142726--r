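#' Assemble the pair feature matrix for one candidate edge
#'
#' Stacks the embedding of the candidate TF, the embedding of the candidate
#' target, and the k pooled rows (in descending-score order) into a
#' `(k + 2) x d` matrix. Row order encodes edge direction, so the matrix for
#' (i, j) differs from (j, i) whenever the two embeddings differ.
#'
#' @param X n-by-d node embedding matrix.
#' @param pool Result of [topk_pool()], or `NULL` for the no-pooling variant
#'   (k = 0, a 2-by-d matrix).
#' @param i,j Node indices of the candidate TF and target (1-based).
#' @return The `(k + 2) x d` pair feature matrix.
#' @export
assemble_pair_matrix <- function(X, pool, i, j) {
  n <- nrow(X)
  if (i < 1 || i > n || j < 1 || j > n) {
    stop("node index out of range: i=", i, ", j=", j, ", n=", n)
  }
  pooled <- if (is.null(pool)) {
    matrix(0, 0, ncol(X))
  } else {
    pool$gated
  }
  rbind(X[i, , drop = FALSE], X[j, , drop = FALSE], pooled,
        deparse.level = 0)
}

#' Assemble pair matrices for a batch of candidate edges
#'
#' Order-preserving map of [assemble_pair_matrix()]; all matrices in the batch
#' share the same pooled rows (one pooling per forward pass).
#'
#' @inheritParams assemble_pair_matrix
#' @param pairs Two-column matrix or data frame of (i, j) node indices.
#' @return A list of `(k + 2) x d` matrices, one per input pair.
#' @export
assemble_batch <- function(X, pool, pairs) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0) stop("pairs must be non-empty")
  lapply(seq_len(nrow(pairs)), function(b) {
    assemble_pair_matrix(X, pool, pairs[b, 1], pairs[b, 2])
  })
}
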