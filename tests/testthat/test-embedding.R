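path_graph <- function(feats) {
  # A - B - C path, undirected neighborhoods
  build_gene_graph(feats, tibble::tibble(tf = c("A", "B"),
                                         target = c("B", "C")))
}

test_that("neighbor aggregation matches the mean/max/empty rules", {
  feats <- rbind(c(0, 0), c(1, 0), c(3, 2))
  rownames(feats) <- c("A", "B", "C")
  g <- build_gene_graph(feats, tibble::tibble(tf = c("A", "A"),
                                              target = c("B", "C")))
  # N(A) = {B, C}
  expect_equal(aggregate_neighbors(feats, g, "mean")[1, ], c(2, 1))
  expect_equal(aggregate_neighbors(feats, g, "max")[1, ], c(3, 2))

  iso <- build_gene_graph(feats, tibble::tibble(tf = "A", target = "B"))
  expect_equal(aggregate_neighbors(feats, iso, "mean")[3, ], c(0, 0))
  expect_equal(aggregate_neighbors(feats, iso, "max")[3, ], c(0, 0))
})

test_that("mean aggregation ignores neighbor order; lstm is seed-reproducible", {
  prob <- random_graph_problem(8, 4, seed = 21)
  a1 <- aggregate_neighbors(prob$feats, prob$graph, "mean")
  # rebuild with edges in reverse order: same sets, same means
  ed <- prob$graph$edges[rev(seq_len(nrow(prob$graph$edges))), ]
  g2 <- build_gene_graph(prob$feats, ed)
  expect_equal(aggregate_neighbors(prob$feats, g2, "mean"), a1)

  lp <- grnlink:::lstm_init(4, seed = 3)
  l1 <- aggregate_neighbors(prob$feats, prob$graph, "lstm", lp, perm_seed = 5)
  l2 <- aggregate_neighbors(prob$feats, prob$graph, "lstm", lp, perm_seed = 5)
  expect_identical(l1, l2)
})

test_that("the SAGE update is ReLU(W . concat(self, aggregate))", {
  feats <- rbind(c(1, 2), c(3, 4), c(0.5, 1))
  rownames(feats) <- c("A", "B", "C")
  g <- path_graph(feats)
  # pass-through of the self part: W = [I; 0]
  W <- rbind(diag(2), matrix(0, 2, 2))
  expect_equal(sage_layer(feats, g, W, "mean"), feats,
               ignore_attr = TRUE)
  # a unit with negative pre-activation is clamped to zero
  W_neg <- cbind(W, c(-1, 0, 0, 0))
  expect_true(all(sage_layer(feats, g, W_neg, "mean")[, 3] == 0))
  expect_error(sage_layer(feats, g, diag(3), "mean"), "concat")
})

test_that("l-hop embeddings depend on exactly the l-hop neighborhood", {
  feats <- matrix(rnorm(3 * 4), 3, 4, dimnames = list(c("A", "B", "C"), NULL))
  g <- path_graph(feats)
  mk_layers <- function(d_in, hops, d = 4) {
    lapply(seq_len(hops), function(t) {
      list(W = glorot_test(2 * ifelse(t == 1, d_in, d), d, seed = 40 + t))
    })
  }
  glorot_test <- function(fi, fo, seed) {
    set.seed(seed)
    matrix(rnorm(fi * fo, sd = 0.3), fi, fo)
  }
  l1 <- mk_layers(4, 1)
  l2 <- mk_layers(4, 2)

  feats2 <- feats
  feats2["C", ] <- feats2["C", ] + 10   # perturb outside A's 1-ball
  g2 <- path_graph(feats2)

  e1 <- embed_genes(feats, g, l1)
  e1p <- embed_genes(feats2, g2, l1)
  expect_equal(e1["A", ], e1p["A", ])   # 1 hop: A cannot see C

  e2 <- embed_genes(feats, g, l2)
  e2p <- embed_genes(feats2, g2, l2)
  expect_false(isTRUE(all.equal(e2["A", ], e2p["A", ])))  # 2 hops: it can

  # no edges: embeddings are a function of own features only
  g0 <- build_gene_graph(feats, tibble::tibble(tf = character(),
                                               target = character()))
  g0p <- build_gene_graph(feats2, tibble::tibble(tf = character(),
                                                 target = character()))
  expect_equal(embed_genes(feats, g0, l2)["A", ],
               embed_genes(feats2, g0p, l2)["A", ])
  expect_error(embed_genes(feats, g, list()), "empty")
})

test_that("top-k pooling scores, selects and gates per the projection rules", {
  X <- rbind(c(1, 0), c(0, 2), c(3, 0))
  got <- topk_pool(X, p = c(1, 0), k = 1)
  expect_equal(got$scores, c(1, 0, 3))
  expect_identical(got$selected, 3L)
  expect_equal(got$gated, rbind(c(3 * tanh(3), 0)), ignore_attr = TRUE)
  expect_equal(got$gated[1, 1], 2.985164, tolerance = 1e-6)

  # score invariance to positive rescaling of p
  expect_equal(topk_pool(X, c(2.7, 0), 1)$scores, got$scores)

  # ties break to the lowest node index
  Xt <- rbind(c(1, 1), c(1, 1), c(1, 1))
  expect_identical(topk_pool(Xt, c(1, 0), 1)$selected, 1L)

  # k = n: all nodes, score-descending then index
  all3 <- topk_pool(X, c(1, 0), 3)
  expect_identical(all3$selected, c(3L, 1L, 2L))

  A <- matrix(1:9, 3)
  expect_identical(dim(topk_pool(X, c(1, 0), 2, adjacency = A)$pruned_adjacency),
                   c(2L, 2L))
  expect_error(topk_pool(X, c(1, 0), 4), "k must lie")
  expect_error(topk_pool(X, c(0, 0), 1), "nonzero")
})
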