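mk_expr <- function(vals, genes = paste0("G", seq_len(nrow(vals)))) {
  dimnames(vals) <- list(genes, paste0("c", seq_len(ncol(vals))))
  vals
}

test_that("node-feature preparation applies log1p and per-gene standardization", {
  m <- mk_expr(rbind(c(0, exp(1) - 1)))
  expect_equal(unname(prepare_node_features(m, TRUE, FALSE)), rbind(c(0, 1)))

  m <- mk_expr(rbind(c(5, 5, 5)))
  expect_equal(unname(prepare_node_features(m, FALSE, TRUE)),
               rbind(c(0, 0, 0)))

  m <- mk_expr(rbind(c(1, 3)))
  expect_equal(unname(prepare_node_features(m, FALSE, TRUE)),
               rbind(c(-1, 1)))
})

test_that("gene graph symmetrizes training positives and treats edges as sets", {
  feats <- mk_expr(matrix(0, 3, 2), genes = c("A", "B", "C"))
  g <- build_gene_graph(feats, tibble::tibble(tf = "A", target = "B"))
  expect_identical(g$neighbors, list(2L, 1L, integer(0)))

  g0 <- build_gene_graph(feats, tibble::tibble(tf = character(),
                                               target = character()))
  expect_true(all(lengths(g0$neighbors) == 0))

  g2 <- build_gene_graph(feats, tibble::tibble(tf = c("A", "B"),
                                               target = c("B", "A")))
  expect_identical(g2$neighbors, g$neighbors)

  gd <- build_gene_graph(feats, tibble::tibble(tf = "A", target = "B"),
                         directed = TRUE)
  expect_identical(gd$neighbors, list(integer(0), 1L, integer(0)))

  expect_error(build_gene_graph(feats, tibble::tibble(tf = "A", target = "Z")),
               "Z")
})

test_that("negative sampling avoids positives, hits the requested count, and is seeded", {
  pos <- tibble::tibble(tf = c("T1", "T1", "T2", "T2", "T3"),
                        target = c("A", "B", "A", "C", "D"))
  neg <- sample_negatives(pos, neg_ratio = 1, seed = 5)
  expect_identical(sum(neg$label == 0), 5L)
  key <- paste(neg$tf, neg$target)
  expect_length(unique(key), nrow(neg))
  negs <- neg[neg$label == 0, ]
  expect_false(any(paste(negs$tf, negs$target) %in% paste(pos$tf, pos$target)))
  expect_true(all(negs$tf %in% pos$tf))
  expect_true(all(negs$target %in% pos$target))

  expect_identical(sample_negatives(pos, 1, seed = 5), neg)
  neg2 <- sample_negatives(pos, 1, seed = 6)
  expect_false(identical(neg, neg2))

  # complete bipartite positives leave no candidates
  full <- tibble::tibble(tf = rep("T1", 2), target = c("A", "B"))
  expect_error(sample_negatives(full, 1, 1), "too small")
})

test_that("fold assignment partitions records with balanced sizes, reproducibly", {
  lab <- tibble::tibble(tf = paste0("T", 1:10), target = paste0("G", 1:10),
                        label = rep(0:1, 5))
  f <- make_folds(lab, 5, seed = 9)
  expect_identical(sort(unique(f$.fold)), 1:5)
  expect_true(all(table(f$.fold) == 2))

  lab11 <- dplyr::bind_rows(lab, lab[1, ])
  f11 <- make_folds(lab11, 5, seed = 9)
  expect_identical(as.integer(sort(table(f11$.fold), decreasing = TRUE)),
                   c(3L, 2L, 2L, 2L, 2L))

  expect_identical(make_folds(lab, 5, seed = 9)$.fold, f$.fold)
  expect_error(make_folds(lab[1:3, ], 5, 1), "exceeds")
})
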