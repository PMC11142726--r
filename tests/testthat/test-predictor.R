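test_that("the learning-rate schedule is exact step decay", {
  expect_identical(lr_at_epoch(0), 0.01)
  expect_identical(lr_at_epoch(10), 0.01 * 0.8)
  expect_equal(lr_at_epoch(25), 0.01 * 0.8^2)
  expect_equal(lr_at_epoch(7, lr0 = 1, decay = 0.5, interval = 2), 0.5^3)
})

test_that("binary cross-entropy matches closed forms and clamps safely", {
  expect_equal(bce_loss(c(0.5, 0.5), c(1, 0)), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(c(0.9, 0.2), c(1, 0)), -(log(0.9) + log(0.8)) / 2,
               tolerance = 1e-12)
  expect_lt(bce_loss(c(1, 0), c(1, 0)), 1e-6)   # perfect prediction limit
  expect_error(bce_loss(c(0.5), c(1, 0)), "length")
})

test_that("pair scoring is a sigmoid probability, deterministic in eval mode", {
  prob <- tiny_problem()
  cfg <- tiny_config(epochs = 1)
  fit <- grn_fit(prob$labeled, prob$graph, cfg)

  X <- matrix(abs(rnorm(5 * 8)), 5, 8)
  pool <- topk_pool(X, rnorm(8), 1)
  E <- assemble_batch(X, pool, rbind(c(1, 2), c(3, 4), c(1, 2)))
  s <- score_pairs(E, fit)
  expect_true(all(s >= 0 & s <= 1))
  expect_identical(s[1], s[3])       # identical inputs, identical scores
  expect_identical(s, score_pairs(E, fit))

  # zeroed head: every logit is 0, every score exactly 0.5
  fit0 <- fit
  for (nm in grep("^(cnn|fc)", names(fit0$params), value = TRUE)) {
    fit0$params[[nm]] <- fit0$params[[nm]] * 0
  }
  expect_equal(score_pairs(E, fit0), rep(0.5, 3))

  expect_error(score_pairs(list(E[[1]], E[[2]][1:2, ]), fit), "shape")
})

test_that("training reduces the loss, is seed-reproducible, and handles epochs = 0", {
  prob <- tiny_problem()
  cfg <- tiny_config(epochs = 8)
  fit <- grn_fit(prob$labeled, prob$graph, cfg)
  tr <- tidy(fit)
  expect_identical(nrow(tr), 8L)
  expect_lt(tr$loss[8], tr$loss[1])
  expect_equal(tr$lr, lr_at_epoch(0:7, cfg$lr0, cfg$lr_decay, cfg$lr_interval))

  fit2 <- grn_fit(prob$labeled, prob$graph, cfg)
  expect_identical(tidy(fit2), tr)
  expect_identical(predict_edges(fit2, prob$labeled),
                   predict_edges(fit, prob$labeled))

  fit0 <- grn_fit(prob$labeled, prob$graph, tiny_config(epochs = 0))
  expect_identical(nrow(tidy(fit0)), 0L)
  p0 <- predict_edges(fit0, prob$labeled[1:4, ])
  expect_true(all(p0$score >= 0 & p0$score <= 1))

  ones <- prob$labeled[prob$labeled$label == 1, ]
  expect_error(grn_fit(ones, prob$graph, cfg), "both positive and negative")
})

test_that("prediction preserves order, rejects unknown genes, repeats exactly", {
  prob <- tiny_problem()
  fit <- grn_fit(prob$labeled, prob$graph, tiny_config(epochs = 2))
  pairs <- prob$labeled[c(5, 1, 3), ]
  p <- predict_edges(fit, pairs)
  expect_identical(p$tf, pairs$tf)
  expect_identical(p$target, pairs$target)
  expect_identical(p, predict_edges(fit, pairs))
  expect_identical(p, predict(fit, pairs))
  expect_error(predict_edges(fit, tibble::tibble(tf = "nope", target = "G001")),
               "nope")
})

test_that("checkpoints round-trip the fitted model exactly", {
  prob <- tiny_problem()
  fit <- grn_fit(prob$labeled, prob$graph, tiny_config(epochs = 2))
  f <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(fit, f)
  back <- read_checkpoint(f)
  expect_identical(back, fit)
  expect_identical(predict_edges(back, prob$labeled),
                   predict_edges(fit, prob$labeled))
  g <- withr::local_tempfile(fileext = ".rds")
  saveRDS(1:3, g)
  expect_error(read_checkpoint(g), "not a grnlink checkpoint")
})

test_that("model summaries expose parameter counts and settings", {
  prob <- tiny_problem()
  fit <- grn_fit(prob$labeled, prob$graph, tiny_config(epochs = 2))
  gl <- glance(fit)
  expect_identical(gl$aggregator, "mean")
  expect_identical(gl$embed_dim, 8L)
  expect_gt(gl$n_parameters, 0)
  expect_s3_class(autoplot(fit), "ggplot")
})
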