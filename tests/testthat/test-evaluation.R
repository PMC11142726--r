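# independent brute-force oracles for the ranking metrics
auroc_oracle <- function(scores, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

auprc_oracle <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  area <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    rec <- tp / sum(labels == 1)
    prec <- tp / sum(pred)
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

test_that("confusion counts follow the >= threshold rule", {
  cm <- confusion(c(0.9, 0.6, 0.4, 0.1), c(1, 0, 1, 0), 0.5)
  expect_identical(unclass(cm)[c("tp", "fp", "tn", "fn")],
                   list(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  cm2 <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0), 0.5)
  expect_identical(cm2$fp + cm2$fn, 0L)
  cm3 <- confusion(rep(0.5, 4), c(1, 0, 1, 0), 0.5)
  expect_identical(cm3$tp + cm3$fp, 4L)   # scores equal to threshold count
  expect_error(confusion(0.5, c(1, 0)), "length")
})

test_that("rate metrics are the four defining ratios with a guarded zero", {
  r <- rates(structure(list(tp = 2L, fp = 1L, tn = 3L, fn = 0L),
                       class = "grn_confusion"))
  expect_equal(r$fpr, 0.25)
  expect_equal(r$tpr, 1)
  expect_equal(r$precision, 2 / 3)
  expect_equal(r$recall, 1)
  expect_identical(r$tpr, r$recall)

  expect_warning(
    r0 <- rates(structure(list(tp = 0L, fp = 0L, tn = 3L, fn = 1L),
                          class = "grn_confusion")),
    "precision")
  expect_identical(r0$precision, 0)
})

test_that("AUROC is the tie-aware pairwise probability", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auroc(c(0.8, 0.6, 0.4), c(1, 0, 1)), 0.5)
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUPRC is the step-wise area over descending thresholds", {
  expect_equal(auprc(c(0.9, 0.8, 0.2), c(1, 1, 0)), 1)
  expect_equal(auprc(c(0.9, 0.8, 0.7, 0.1), c(0, 0, 0, 1)), 0.25)
  expect_error(auprc(c(0.1, 0.2), c(0, 0)), "at least one positive")
})

test_that("ranking metrics agree with brute-force oracles on random instances", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(4:25, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))  # both classes guaranteed
    scores <- round(runif(n), sample(1:3, 1)) # rounding forces ties
    expect_equal(auroc(scores, labels), auroc_oracle(scores, labels))
    expect_equal(auprc(scores, labels), auprc_oracle(scores, labels))
  }
})

test_that("edge categories restate the confusion partition", {
  scores <- c(0.9, 0.6, 0.4, 0.1)
  labels <- c(1, 0, 1, 0)
  cats <- categorize_edges(scores, labels, 0.5)
  expect_identical(cats, c("red", "extra", "green", "blue"))
  cm <- confusion(scores, labels, 0.5)
  expect_identical(sum(cats == "red"), cm$tp)
  expect_identical(sum(cats == "green"), cm$fn)
  expect_identical(sum(cats == "blue"), cm$tn)
  expect_identical(sum(cats == "extra"), cm$fp)

  perfect <- categorize_edges(c(1, 1, 0), c(1, 1, 0), 0.5)
  expect_false(any(perfect %in% c("green", "extra")))

  set.seed(8)
  s <- runif(40)
  y <- rbinom(40, 1, 0.5)
  expect_length(categorize_edges(s, y, 0.5), 40)
})

test_that("cross-validation aggregates fold metrics by arithmetic mean", {
  prob <- tiny_problem()
  cv <- cross_validate(prob$labeled, prob$expr,
                       tiny_config(epochs = 1, n_folds = 3))
  expect_identical(nrow(tidy(cv)), 3L)
  expect_equal(glance(cv)$auroc, mean(tidy(cv)$auroc))
  expect_equal(glance(cv)$auprc, mean(tidy(cv)$auprc))
  expect_equal(glance(cv)$precision, mean(tidy(cv)$precision))
  # every record is tested exactly once
  expect_identical(nrow(cv$predictions), nrow(prob$labeled))
  expect_s3_class(autoplot(cv), "ggplot")

  # the minimal protocol runs: 2 folds over 4 records (seed chosen so the
  # random deal puts both classes in each fold)
  lab4 <- prob$labeled[c(1, 2, nrow(prob$labeled) - 1, nrow(prob$labeled)), ]
  seed2 <- Find(function(s) {
    f <- make_folds(lab4, 2, s)
    all(tapply(f$label, f$.fold, function(x) length(unique(x))) == 2)
  }, 1:50)
  cv2 <- cross_validate(lab4, prob$expr,
                        tiny_config(epochs = 1, n_folds = 2, seed = seed2))
  expect_identical(nrow(tidy(cv2)), 2L)
})

test_that("metric reports are written with fold rows plus a mean row", {
  prob <- tiny_problem()
  cv <- cross_validate(prob$labeled, prob$expr,
                       tiny_config(epochs = 1, n_folds = 2))
  dir <- withr::local_tempdir()
  write_metrics_report(cv, dir)
  tab <- read.csv(file.path(dir, "metrics.csv"))
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$fold, c("1", "2", "mean"))
  cats <- read.csv(file.path(dir, "edge_categories.csv"))
  expect_identical(sort(names(cats)),
                   sort(c("TF", "target", "score", "label", "category")))
})
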