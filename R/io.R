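#' Read a genes-by-cells expression matrix
#'
#' Reads a BEELINE-style `ExpressionData.csv`: the first row holds cell
#' identifiers, the first column holds gene identifiers, and every value is a
#' non-negative finite number. Row and column order are preserved exactly as
#' written.
#'
#' @param path Path to the delimited file.
#' @param delimiter Field separator (default `","`; use `"\t"` for TSV).
#' @return A numeric matrix with gene ids as rownames and cell ids as
#'   colnames.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_expression(matrix(1:4, 2, dimnames = list(c("G1", "G2"),
#'                                                 c("c1", "c2"))), f)
#' read_expression(f)
read_expression <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, row.names = NULL,
                          colClasses = "character",
                          stringsAsFactors = FALSE, quote = "\"")
  if (ncol(df) < 3) stop("expression file needs >= 2 cell columns: ", path)
  gene_ids <- df[[1]]
  cell_ids <- colnames(df)[-1]
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g) > 0) {
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(dup_g), collapse = ", "))
  }
  dup_c <- cell_ids[duplicated(cell_ids)]
  if (length(dup_c) > 0) {
    stop("duplicate cell id(s) in ", path, ": ",
         paste(unique(dup_c), collapse = ", "))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim(vals)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric or non-finite expression value at gene '%s', cell '%s'",
                 gene_ids[bad[1, 1]], cell_ids[bad[1, 2]]))
  }
  neg <- which(num < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative expression value at gene '%s', cell '%s'",
                 gene_ids[neg[1, 1]], cell_ids[neg[1, 2]]))
  }
  if (nrow(num) < 2) stop("expression matrix needs >= 2 genes")
  dimnames(num) <- list(gene_ids, cell_ids)
  num
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]; values are written with 17 significant
#' digits so a read-write-read round trip reproduces the matrix bit for bit.
#'
#' @param mat Numeric matrix with gene rownames and cell colnames.
#' @param path Output path.
#' @param delimiter Field separator.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, delimiter = ",") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  header <- paste(c("", colnames(mat)), collapse = delimiter)
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], sprintf("%.17g", mat[i, ])),
          collapse = delimiter)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a directed reference network
#'
#' Reads a two-column edge list (BEELINE `refNetwork.csv` dialect:
#' `Gene1,Gene2` = regulator, target; the header is optional). Duplicate pairs
#' are removed and self-loops are dropped unless `keep_self_loops = TRUE`;
#' both removals are reported with a message. Gene identifiers are treated as
#' case-sensitive exact strings.
#'
#' @param path Path to the edge-list file.
#' @param delimiter Field separator.
#' @param keep_self_loops Retain `G -> G` edges (default drop).
#' @return A tibble with columns `tf` and `target`, in file order.
#' @export
read_network <- function(path, delimiter = ",", keep_self_loops = FALSE) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(tf = character(), target = character()))
  }
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  if (any(lengths(fields) < 2)) {
    stop("network file must have at least two columns: ", path)
  }
  tf <- trimws(vapply(fields, `[[`, character(1), 1))
  target <- trimws(vapply(fields, `[[`, character(1), 2))
  if (tolower(tf[1]) == "gene1" && tolower(target[1]) == "gene2") {
    tf <- tf[-1]
    target <- target[-1]
  }
  edges <- tibble::tibble(tf = tf, target = target)
  n0 <- nrow(edges)
  edges <- dplyr::distinct(edges, .data$tf, .data$target)
  n_dup <- n0 - nrow(edges)
  if (n_dup > 0) message(n_dup, " duplicate edge(s) removed")
  if (!keep_self_loops) {
    n1 <- nrow(edges)
    edges <- dplyr::filter(edges, .data$tf != .data$target)
    n_loop <- n1 - nrow(edges)
    if (n_loop > 0) message(n_loop, " self-loop(s) removed")
  }
  edges
}

#' Write a ranked edge list
#'
#' Writes `TF,target,score` rows sorted by score descending; ties are broken
#' by `(tf, target)` lexicographic (C-locale) order so output is fully
#' deterministic.
#'
#' @param ranked A data frame with columns `tf`, `target`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranked_edges <- function(ranked, path) {
  stopifnot(all(c("tf", "target", "score") %in% names(ranked)))
  if (any(ranked$score < 0 | ranked$score > 1)) {
    stop("edge scores must lie in [0, 1]")
  }
  ord <- order(-ranked$score, ranked$tf, ranked$target, method = "radix")
  ranked <- ranked[ord, c("tf", "target", "score")]
  lines <- c("TF,target,score",
             sprintf("%s,%s,%.17g", ranked$tf, ranked$target, ranked$score))
  writeLines(lines, path)
  invisible(path)
}
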