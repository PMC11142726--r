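test_that("planted networks hit the requested mean out-degree with TF sources", {
  grand <- vapply(1:300, function(s) {
    nrow(generate_grn(100, 10, 5, seed = s)$edges) / 10
  }, numeric(1))
  expect_lt(abs(mean(grand) - 5) / 5, 0.1)

  net <- generate_grn(50, 5, 4, seed = 7)
  expect_true(all(net$edges$tf %in% net$tf_ids))
  expect_false(any(net$edges$tf == net$edges$target))
  expect_false(any(duplicated(paste(net$edges$tf, net$edges$target))))
  expect_identical(generate_grn(50, 5, 4, seed = 7)$edges, net$edges)
  expect_error(generate_grn(10, 12, 3, 1), "n_tfs")
})

test_that("noise-free regulation gives perfect rank correlation with the stated sign", {
  base <- generate_grn(10, 2, 1, seed = 3)
  for (sgn in c(1, -1)) {
    net <- base
    net$edges <- tibble::tibble(tf = "G001", target = "G005",
                                sign = sgn, weight = 1)
    expr <- simulate_expression(net, n_cells = 200, noise_sd = 0, seed = 11)
    rho <- cor(expr["G001", ], expr["G005", ], method = "spearman")
    expect_equal(rho, sgn)
  }
})

test_that("noisy regulation still beats the permutation null", {
  net <- generate_grn(10, 2, 1, seed = 3)
  net$edges <- tibble::tibble(tf = "G001", target = "G005",
                              sign = 1, weight = 1)
  expr <- simulate_expression(net, n_cells = 500, noise_sd = 0.5, seed = 13)
  obs <- abs(cor(expr["G001", ], expr["G005", ], method = "spearman"))
  set.seed(17)
  null <- replicate(1000, {
    abs(cor(expr["G001", ], sample(expr["G005", ]), method = "spearman"))
  })
  expect_gt(obs, quantile(null, 0.975))
})

test_that("the canonical fixture has the preset shape and regenerates byte-identically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  fx1 <- make_fixture(dir1)
  fx2 <- make_fixture(dir2)
  expect_identical(dim(fx1$expr), c(100L, 200L))
  expect_gt(nrow(fx1$network), 0)
  expect_true(all(fx1$network$tf %in% fx1$net$tf_ids))
  expect_identical(readLines(fx1$expr_path), readLines(fx2$expr_path))
  expect_identical(readLines(fx1$net_path), readLines(fx2$net_path))
  # the written files re-read to the in-memory objects
  expect_identical(read_expression(fx1$expr_path), fx1$expr)
  expect_identical(read_network(fx1$net_path), fx1$network)
})
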