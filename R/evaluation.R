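#' Confusion counts at a score threshold
#'
#' A pair is predicted positive iff its score is `>= threshold`.
#'
#' @param scores Predicted probabilities.
#' @param labels True labels in `{0, 1}`.
#' @param threshold Decision threshold in (0, 1).
#' @return A list of class `"grn_confusion"` with integer `tp`, `fp`, `tn`,
#'   `fn` summing to `length(scores)`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length")
  }
  stopifnot(threshold > 0, threshold < 1)
  pred <- scores >= threshold
  structure(list(tp = sum(pred & labels == 1),
                 fp = sum(pred & labels == 0),
                 tn = sum(!pred & labels == 0),
                 fn = sum(!pred & labels == 1)),
            class = "grn_confusion")
}

#' Rate metrics from confusion counts
#'
#' False positive rate `FP / (FP + TN)`, true positive rate `TP / (TP + FN)`,
#' precision `TP / (TP + FP)` and recall `TP / (TP + FN)` (recall and TPR are
#' the same ratio). A zero denominator yields 0 with a warning.
#'
#' @param cm A `"grn_confusion"` from [confusion()].
#' @return Named list `fpr`, `tpr`, `precision`, `recall`.
#' @export
rates <- function(cm) {
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; returning 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  tpr <- safe_div(cm$tp, cm$tp + cm$fn, "TPR/recall")
  list(fpr = safe_div(cm$fp, cm$fp + cm$tn, "FPR"),
       tpr = tpr,
       precision = safe_div(cm$tp, cm$tp + cm$fp, "precision"),
       recall = tpr)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a random positive outscores
#' a random negative, with ties counted one half — exactly the rank-statistic
#' form of the ROC area.
#'
#' @param scores Predicted scores.
#' @param labels True labels in `{0, 1}` (both classes required).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("auroc needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise summation over descending unique score thresholds: at each
#' threshold the recall increment is weighted by the precision there (the
#' non-interpolated area, identical to average precision).
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0) stop("auprc needs at least one positive")
  ord <- order(-scores)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  # evaluate only at the last index of each tied-score run
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / n1
  sum(diff(c(0, rec)) * prec)
}

#' Classify evaluated edges into report categories
#'
#' True positives are `"red"` (in the reference network and predicted),
#' false negatives `"green"` (in the reference network but missed), true
#' negatives `"blue"` (absent and correctly rejected), and false positives
#' `"extra"` (absent but predicted — a category the three-color report
#' convention leaves unnamed).
#'
#' @inheritParams confusion
#' @return Character vector of categories, aligned with `scores`.
#' @export
categorize_edges <- function(scores, labels, threshold = 0.5) {
  pred <- scores >= threshold
  dplyr::case_when(
    labels == 1 & pred ~ "red",
    labels == 1 & !pred ~ "green",
    labels == 0 & !pred ~ "blue",
    TRUE ~ "extra"
  )
}

fold_metrics <- function(scores, labels, threshold) {
  cm <- confusion(scores, labels, threshold)
  rt <- suppressWarnings(rates(cm))
  tibble::tibble(tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
                 fpr = rt$fpr, tpr = rt$tpr,
                 precision = rt$precision, recall = rt$recall,
                 auroc = auroc(scores, labels),
                 auprc = auprc(scores, labels))
}

#' Leakage-safe k-fold cross-validation
#'
#' Mixes the labeled positive and negative edges, deals them into
#' `config$n_folds` folds, and for each fold trains on the other folds and
#' scores the held-out one. The aggregation graph for each fold is built from
#' that fold's *training positives only*, so no test-fold edge ever
#' contributes to the embeddings. Per-fold seeds derive from `config$seed`
#' and the fold index. Metrics are averaged arithmetically across folds.
#'
#' @param labeled Data frame of labeled edges (`tf`, `target`, `label`), e.g.
#'   from [sample_negatives()].
#' @param expr Genes-by-cells expression matrix covering every gene in
#'   `labeled`.
#' @param config A [grn_config()].
#' @return An object of class `"grn_cv"`: per-fold metrics (`$metrics`),
#'   their means (`$summary`), per-edge predictions with fold assignments and
#'   categories (`$predictions`), and per-fold training-graph edge tables
#'   (`$fold_graphs`).
#' @export
cross_validate <- function(labeled, expr, config = grn_config()) {
  features <- prepare_node_features(expr, config$log_transform,
                                    config$standardize)
  folded <- make_folds(labeled, config$n_folds, config$seed)
  metrics <- vector("list", config$n_folds)
  preds <- vector("list", config$n_folds)
  fold_graphs <- vector("list", config$n_folds)
  for (f in seq_len(config$n_folds)) {
    train <- folded[folded$.fold != f, ]
    test <- folded[folded$.fold == f, ]
    graph <- build_gene_graph(features, train[train$label == 1, ],
                              directed = config$directed_neighbors)
    fold_graphs[[f]] <- graph$edges
    cfg_f <- config
    cfg_f$seed <- derive_seed(config$seed, "fold", f)
    fit <- grn_fit(train, graph, cfg_f)
    sc <- predict_edges(fit, test)
    metrics[[f]] <- dplyr::bind_cols(tibble::tibble(fold = f),
                                     fold_metrics(sc$score, test$label,
                                                  config$threshold))
    preds[[f]] <- tibble::tibble(
      fold = f, tf = test$tf, target = test$target,
      label = test$label, score = sc$score,
      category = categorize_edges(sc$score, test$label, config$threshold))
  }
  metrics <- dplyr::bind_rows(metrics)
  summary <- dplyr::summarise(metrics, dplyr::across(-"fold", mean))
  structure(list(metrics = metrics, summary = summary,
                 predictions = dplyr::bind_rows(preds),
                 fold_graphs = fold_graphs,
                 fold_assignments = folded$.fold,
                 config = config),
            class = "grn_cv")
}

#' @export
print.grn_cv <- function(x, ...) {
  cat(sprintf("<grn_cv> %d folds over %d labeled edges\n",
              nrow(x$metrics), length(x$fold_assignments)))
  cat(sprintf("  mean AUROC %.3f, mean AUPRC %.3f\n",
              x$summary$auroc, x$summary$auprc))
  invisible(x)
}

#' Write a cross-validation metrics report
#'
#' Emits the per-fold table with an appended `mean` row as CSV, plus the
#' per-edge category table (`TF,target,score,label,category`).
#'
#' @param cv A `"grn_cv"` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_metrics_report <- function(cv, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- dplyr::bind_rows(
    dplyr::mutate(cv$metrics, fold = as.character(.data$fold)),
    dplyr::bind_cols(tibble::tibble(fold = "mean"), cv$summary))
  utils::write.csv(tab, file.path(dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(
    dplyr::select(cv$predictions, TF = "tf", target = "target",
                  score = "score", label = "label", category = "category"),
    file.path(dir, "edge_categories.csv"), row.names = FALSE)
  invisible(dir)
}
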