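#' Prepare node features from an expression matrix
#'
#' Optionally applies `log(1 + x)` and then per-gene standardization (mean 0,
#' variance 1 across cells, using the population variance). Constant rows
#' standardize to all zeros rather than NaN.
#'
#' @param expr Genes-by-cells numeric matrix.
#' @param log_transform Apply `log1p`?
#' @param standardize Center and scale each gene row?
#' @return A numeric matrix of the same shape and dimnames.
#' @export
prepare_node_features <- function(expr, log_transform = TRUE,
                                  standardize = TRUE) {
  x <- expr
  if (log_transform) x <- log1p(x)
  if (standardize) {
    mu <- rowMeans(x)
    v <- rowMeans(x^2) - mu^2
    v <- pmax(v, 0)
    s <- sqrt(v)
    x <- (x - mu) / ifelse(s > 0, s, 1)
    x[s == 0, ] <- 0
  }
  x
}

#' Build the gene graph used for neighborhood aggregation
#'
#' Nodes are the genes of the feature matrix; the aggregation neighborhoods
#' come from the supplied positive training edges. By default the directed
#' TF-to-target edges are symmetrized (regulators see their targets and vice
#' versa, the common GraphSAGE convention); with `directed = TRUE` a gene
#' aggregates only its incoming regulators. Genes touched by no edge get an
#' empty neighborhood and aggregate to the zero vector.
#'
#' @param features Genes-by-features numeric matrix with gene rownames
#'   (typically from [prepare_node_features()]).
#' @param edges Data frame of positive edges with columns `tf`, `target`.
#' @param directed Use directed (incoming-only) neighborhoods?
#' @return An object of class `"gene_graph"`: node count, per-node neighbor
#'   index sets, the feature matrix, and the edge table it was built from.
#' @export
build_gene_graph <- function(features, edges, directed = FALSE) {
  stopifnot(is.matrix(features), !is.null(rownames(features)))
  gene_ids <- rownames(features)
  n <- nrow(features)
  unknown <- setdiff(unique(c(edges$tf, edges$target)), gene_ids)
  if (length(unknown) > 0) {
    stop("edge gene id(s) not present in the expression matrix: ",
         paste(unknown, collapse = ", "))
  }
  ti <- match(edges$tf, gene_ids)
  tj <- match(edges$target, gene_ids)
  neighbors <- vector("list", n)
  for (v in seq_len(n)) neighbors[[v]] <- integer(0)
  if (length(ti) > 0) {
    if (directed) {
      src <- ti
      dst <- tj
    } else {
      src <- c(ti, tj)
      dst <- c(tj, ti)
    }
    sp <- split(src, dst)
    for (nm in names(sp)) {
      v <- as.integer(nm)
      nb <- sort(unique(sp[[nm]]))
      neighbors[[v]] <- nb[nb != v]
    }
  }
  structure(list(n_nodes = n, neighbors = neighbors, features = features,
                 gene_ids = gene_ids,
                 edges = tibble::tibble(tf = edges$tf, target = edges$target),
                 directed = directed),
            class = "gene_graph")
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("<gene_graph> %d nodes, %d directed edges, %s neighborhoods\n",
              x$n_nodes, nrow(x$edges),
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

#' Label positive edges and sample negative edges
#'
#' Positives are the reference-network edges; negatives are drawn uniformly
#' without replacement from the TF-pool x target-pool candidate space minus
#' the positives and self-pairs (TF and target roles are defined by
#' appearance in the reference network). Sampling is deterministic given
#' `seed`.
#'
#' @param positives Data frame of reference edges (`tf`, `target`).
#' @param neg_ratio Negatives per positive (default 1, equal-sized classes).
#' @param seed Integer seed for the sampling substream.
#' @return A tibble `tf, target, label` (label 1 = positive, 0 = sampled
#'   negative) with the TF and target pools attached as attributes
#'   `tf_pool` / `target_pool`.
#' @export
sample_negatives <- function(positives, neg_ratio = 1, seed = 1L) {
  stopifnot(nrow(positives) > 0, neg_ratio > 0)
  tf_pool <- unique(positives$tf)
  target_pool <- unique(positives$target)
  cand_tf <- rep(tf_pool, each = length(target_pool))
  cand_tg <- rep(target_pool, times = length(tf_pool))
  keep <- cand_tf != cand_tg &
    !(paste0(cand_tf, "\r", cand_tg) %in%
        paste0(positives$tf, "\r", positives$target))
  cand_tf <- cand_tf[keep]
  cand_tg <- cand_tg[keep]
  n_neg <- ceiling(neg_ratio * nrow(positives))
  if (length(cand_tf) < n_neg) {
    stop(sprintf(
      "negative candidate space too small: %d available, %d requested",
      length(cand_tf), n_neg))
  }
  pick <- with_seed(derive_seed(seed, "negatives"),
                    sample.int(length(cand_tf), n_neg))
  labeled <- tibble::tibble(
    tf = c(positives$tf, cand_tf[pick]),
    target = c(positives$target, cand_tg[pick]),
    label = c(rep(1L, nrow(positives)), rep(0L, n_neg))
  )
  attr(labeled, "tf_pool") <- tf_pool
  attr(labeled, "target_pool") <- target_pool
  labeled
}

#' Assign cross-validation folds
#'
#' Records are shuffled by the seeded substream and dealt round-robin, so fold
#' sizes differ by at most one and the assignment is reproducible.
#'
#' @param labeled Data frame of labeled edges.
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return `labeled` with an integer `.fold` column in `1:n_folds`.
#' @export
make_folds <- function(labeled, n_folds = 5L, seed = 1L) {
  n <- nrow(labeled)
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (n_folds > n) stop("n_folds (", n_folds, ") exceeds record count (", n, ")")
  perm <- with_seed(derive_seed(seed, "folds"), sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep_len(seq_len(n_folds), n)
  labeled$.fold <- fold
  labeled
}
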