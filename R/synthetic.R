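# Planted-network simulator. A designated subset of genes act as TFs with
# heavy-tailed out-degrees (hub structure); each regulated gene's latent
# value is a signed weighted sum of its regulators' activities plus noise,
# pushed through a monotone exp map to non-negative "expression". The point
# is detectable, analyzable regulator-target dependence, not kinetic realism.

#' Generate a planted gene regulatory network
#'
#' TF out-degrees are drawn from a power-law with exponent 2 truncated at
#' `n_genes - 1`, then rescaled so their expectation matches
#' `mean_out_degree`. Targets are sampled uniformly without replacement
#' (never the TF itself); edge signs are +/-1 with probability one half and
#' weights are uniform on [0.5, 1.5].
#'
#' @param n_genes Total number of genes.
#' @param n_tfs Number of genes designated as TFs (`1 <= n_tfs < n_genes`).
#' @param mean_out_degree Requested mean TF out-degree.
#' @param seed Integer seed; the same seed reproduces the network exactly.
#' @return A list of class `"planted_grn"`: `gene_ids`, `tf_ids`, and an
#'   `edges` tibble (`tf`, `target`, `sign`, `weight`).
#' @export
generate_grn <- function(n_genes = 100L, n_tfs = 10L, mean_out_degree = 5,
                         seed = 1L) {
  stopifnot(n_tfs >= 1, n_tfs < n_genes, mean_out_degree >= 1)
  max_deg <- n_genes - 1L
  if (mean_out_degree > max_deg) {
    stop("mean_out_degree ", mean_out_degree, " infeasible for ",
         n_genes, " genes")
  }
  gene_ids <- sprintf("G%03d", seq_len(n_genes))
  tf_ids <- gene_ids[seq_len(n_tfs)]
  pmf <- (seq_len(max_deg))^-2
  pmf <- pmf / sum(pmf)
  scale <- mean_out_degree / sum(seq_len(max_deg) * pmf)
  with_seed(derive_seed(seed, "grn"), {
    raw <- sample.int(max_deg, n_tfs, replace = TRUE, prob = pmf)
    deg <- pmin(pmax(round(scale * raw), 1L), max_deg)
    edges <- dplyr::bind_rows(lapply(seq_len(n_tfs), function(t) {
      pool <- setdiff(gene_ids, tf_ids[t])
      tibble::tibble(tf = tf_ids[t], target = sample(pool, deg[t]))
    }))
    edges$sign <- sample(c(-1, 1), nrow(edges), replace = TRUE)
    edges$weight <- stats::runif(nrow(edges), 0.5, 1.5)
  })
  structure(list(gene_ids = gene_ids, tf_ids = tf_ids, edges = edges,
                 seed = seed),
            class = "planted_grn")
}

#' Simulate an expression matrix from a planted network
#'
#' Per cell, every TF gets an i.i.d. standard-normal activity; a regulated
#' gene's latent value is the signed weighted sum of its regulators'
#' activities plus Gaussian noise; unregulated non-TF genes are pure noise.
#' Latent values are mapped through `10 * exp(x)` — monotone, so regulator-
#' target dependence survives as rank correlation — to keep expression
#' non-negative.
#'
#' @param net A `"planted_grn"` from [generate_grn()].
#' @param n_cells Number of cells (>= 2).
#' @param noise_sd Standard deviation of the additive latent noise (>= 0).
#' @param seed Integer seed.
#' @return A genes-by-cells expression matrix with gene/cell dimnames.
#' @export
simulate_expression <- function(net, n_cells = 200L, noise_sd = 0.5,
                                seed = 1L) {
  stopifnot(inherits(net, "planted_grn"), n_cells >= 2, noise_sd >= 0)
  n <- length(net$gene_ids)
  with_seed(derive_seed(seed, "expr"), {
    act <- matrix(stats::rnorm(length(net$tf_ids) * n_cells),
                  nrow = length(net$tf_ids),
                  dimnames = list(net$tf_ids, NULL))
    latent <- matrix(0, n, n_cells, dimnames = list(net$gene_ids, NULL))
    latent[net$tf_ids, ] <- act
    regulated <- unique(net$edges$target)
    for (g in regulated) {
      e <- net$edges[net$edges$target == g, ]
      latent[g, ] <- latent[g, ] +
        drop(crossprod(act[e$tf, , drop = FALSE], e$sign * e$weight))
    }
    noisy <- union(regulated, setdiff(net$gene_ids, net$tf_ids))
    if (noise_sd > 0) {
      latent[noisy, ] <- latent[noisy, ] +
        matrix(stats::rnorm(length(noisy) * n_cells, sd = noise_sd),
               length(noisy), n_cells)
    }
  })
  expr <- 10 * exp(latent)
  colnames(expr) <- sprintf("C%03d", seq_len(n_cells))
  expr
}

#' The canonical desk-scale test fixture
#'
#' Generates the package's standard planted benchmark — 100 genes of which 10
#' are TFs, mean out-degree 5, 200 cells, latent noise 0.5 — and optionally
#' writes `ExpressionData.csv` / `refNetwork.csv` in the package's file
#' dialects. Regenerating with the same seed is byte-identical.
#'
#' @param dir Output directory for the two files, or `NULL` to skip writing.
#' @param seed Integer seed (default 1).
#' @return A list: `expr` (matrix), `network` (tibble `tf`, `target`),
#'   `net` (the full `"planted_grn"`), and the file paths if written.
#' @export
make_fixture <- function(dir = NULL, seed = 1L) {
  net <- generate_grn(n_genes = 100L, n_tfs = 10L, mean_out_degree = 5,
                      seed = seed)
  expr <- simulate_expression(net, n_cells = 200L, noise_sd = 0.5,
                              seed = seed)
  out <- list(expr = expr,
              network = dplyr::select(net$edges, "tf", "target"),
              net = net)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    expr_path <- file.path(dir, "ExpressionData.csv")
    net_path <- file.path(dir, "refNetwork.csv")
    write_expression(expr, expr_path)
    writeLines(c("Gene1,Gene2",
                 paste(net$edges$tf, net$edges$target, sep = ",")),
               net_path)
    out$expr_path <- expr_path
    out$net_path <- net_path
  }
  out
}
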