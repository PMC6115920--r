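## Median-of-ratios normalization of tissue expression matrices and seeded
## Lloyd's K-means clustering into expression level classes.

#' Read a genes x tissues expression matrix
#'
#' @param path TSV with a gene-id first column and one column per tissue;
#'   values must be nonnegative.
#' @return Numeric matrix, genes in rows.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  storage.mode(mat) <- "double"
  if (any(mat < 0)) stop("expression values must be nonnegative")
  mat
}

#' Median-of-ratios size factors
#'
#' For each tissue j, the size factor is the median over reference genes of
#' `value[i, j] / geometric_mean(value[i, ])`; the reference set is the
#' genes with all-positive values across tissues. Normalized values are
#' `value / factor`.
#'
#' @param mat Genes x tissues matrix of nonnegative values.
#' @param pseudocount Optional constant added before estimation when no
#'   gene is positive everywhere.
#' @return Named numeric vector of per-tissue factors.
#' @export
size_factors <- function(mat, pseudocount = 0) {
  stopifnot(is.matrix(mat))
  m <- mat + pseudocount
  ref <- which(apply(m, 1L, function(v) all(v > 0)))
  if (length(ref) == 0L) {
    stop("no gene with all-positive values; consider a pseudocount")
  }
  loggeo <- rowMeans(log(m[ref, , drop = FALSE]))
  sf <- apply(m[ref, , drop = FALSE], 2L,
              function(col) stats::median(exp(log(col) - loggeo)))
  stats::setNames(sf, colnames(mat))
}

#' Apply size factors
#' @param mat Genes x tissues matrix.
#' @param sf Per-tissue factors from [size_factors()].
#' @return Normalized matrix.
#' @export
normalize_expression <- function(mat, sf = size_factors(mat)) {
  sweep(mat, 2L, sf, "/")
}

#' Seeded Lloyd's K-means on expression profiles
#'
#' Rows are sorted by gene id before seeding so the result depends only on
#' the seed and the data, never on input row order. Initialization picks k
#' distinct genes uniformly; iteration alternates Euclidean assignment and
#' centroid update until assignments stabilise or `max_iter` is reached.
#' An empty cluster is re-seeded to the point farthest from its assigned
#' centroid. The within-cluster sum of squares is non-increasing across
#' iterations.
#'
#' @param mat Normalized genes x tissues matrix with row names.
#' @param k Number of clusters.
#' @param max_iter Iteration cap (default 1000).
#' @param seed Integer seed.
#' @return List `cluster` (named integer vector), `centers` (k x tissues),
#'   `wss` (per-iteration objective trace), `iterations`, `tot_withinss`.
#' @export
kmeans_cluster <- function(mat, k = 3L, max_iter = 1000L, seed = 1L) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (k > nrow(mat)) stop("k exceeds the number of genes")
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  n <- nrow(mat)
  set.seed(seed)
  centers <- mat[sample.int(n, k), , drop = FALSE]
  rownames(centers) <- NULL
  assign_prev <- rep(0L, n)
  wss_trace <- numeric(0)
  d2 <- matrix(0, n, k)
  for (iter in seq_len(max_iter)) {
    for (c in seq_len(k)) {
      d2[, c] <- rowSums(sweep(mat, 2L, centers[c, ], "-")^2)
    }
    assign <- max.col(-d2, ties.method = "first")
    ## re-seed empty clusters to the farthest point from its centroid
    for (c in which(tabulate(assign, k) == 0L)) {
      far <- which.max(d2[cbind(seq_len(n), assign)])
      centers[c, ] <- mat[far, ]
      assign[far] <- c
      d2[, c] <- rowSums(sweep(mat, 2L, centers[c, ], "-")^2)
    }
    wss_trace <- c(wss_trace,
                   sum(d2[cbind(seq_len(n), assign)]))
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
    for (c in seq_len(k)) {
      centers[c, ] <- colMeans(mat[assign == c, , drop = FALSE])
    }
  }
  list(cluster = stats::setNames(assign, rownames(mat)), centers = centers,
       wss = wss_trace, iterations = iter,
       tot_withinss = wss_trace[length(wss_trace)])
}

EXPRESSION_LEVEL_LABELS <- c("moderate-to-minimal", "minimal-to-basal",
                             "basal-to-none")

#' Label k = 3 expression clusters by level
#'
#' Clusters are ranked by mean centroid magnitude (ties broken by cluster
#' index) and labelled, in descending order, moderate-to-minimal,
#' minimal-to-basal and basal-to-none.
#'
#' @param fit Result of [kmeans_cluster()] with k = 3.
#' @return List `labels` (per-gene character vector) and `cluster_labels`
#'   (label of each cluster index).
#' @export
classify_expression_levels <- function(fit) {
  if (nrow(fit$centers) != 3L) stop("expression level labels need k = 3")
  means <- rowMeans(fit$centers)
  ord <- order(means, decreasing = TRUE)   # stable: ties by index
  cluster_labels <- character(3L)
  cluster_labels[ord] <- EXPRESSION_LEVEL_LABELS
  list(labels = stats::setNames(cluster_labels[fit$cluster],
                                names(fit$cluster)),
       cluster_labels = cluster_labels)
}
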