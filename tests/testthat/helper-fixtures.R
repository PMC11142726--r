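# Shared builders for desk-scale test problems. Everything is generated in
# code; the canonical planted fixture is cached per test run because several
# files use it.

tiny_problem <- function(n_genes = 20, n_tfs = 4, n_cells = 30, seed = 2,
                         neg_ratio = 1) {
  net <- generate_grn(n_genes, n_tfs, mean_out_degree = 3, seed = seed)
  expr <- simulate_expression(net, n_cells = n_cells, noise_sd = 0.5,
                              seed = seed)
  labeled <- sample_negatives(net$edges[, c("tf", "target")], neg_ratio, seed)
  feats <- prepare_node_features(expr)
  graph <- build_gene_graph(feats, labeled[labeled$label == 1, ])
  list(net = net, expr = expr, labeled = labeled, feats = feats,
       graph = graph)
}

tiny_config <- function(...) {
  args <- list(embed_dim = 8, fc_hidden = 8, epochs = 3, seed = 3)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(grn_config, args)
}

.fixture_cache <- new.env(parent = emptyenv())

canonical_fixture <- function(seed = 1) {
  key <- paste0("fx", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- make_fixture(seed = seed)
  }
  .fixture_cache[[key]]
}

# random small graph + features for oracle comparisons
random_graph_problem <- function(n, d, seed) {
  feats <- with(list(), {
    set.seed(seed)
    matrix(rnorm(n * d), n, d,
           dimnames = list(sprintf("g%02d", seq_len(n)), NULL))
  })
  n_edges <- sample(1:(n * 2), 1)
  tf <- sprintf("g%02d", sample(n, n_edges, replace = TRUE))
  tg <- sprintf("g%02d", sample(n, n_edges, replace = TRUE))
  keep <- tf != tg
  edges <- tibble::tibble(tf = tf[keep], target = tg[keep])
  edges <- dplyr::distinct(edges)
  list(feats = feats, graph = build_gene_graph(feats, edges))
}
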