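# Co-expression network reconstruction from cluster-pair DE z-scores.
#
# With X cell clusters there are X(X-1)/2 unordered cluster pairs; each pair
# yields one signed DE z-score per gene, and gene-gene correlations are then
# computed on these z-score profiles rather than on raw expression.

#' Cluster-pair differential-expression z-scores
#'
#' For every unordered pair of cell clusters (a, b), a < b in label order,
#' computes a signed per-gene z-score measuring the expression shift between
#' the two clusters (positive = higher in cluster a). The statistic is the
#' Wilcoxon rank-sum normal approximation with tie correction (robust to the
#' zero inflation of droplet scRNA-seq); a Welch t alternative is available.
#'
#' @param expr an [expression_matrix()].
#' @param clustering data frame with columns `cell_id`, `cluster` covering all
#'   cells of `expr` (extra rows ignored).
#' @param method `"wilcoxon"` (default) or `"welch"`.
#'
#' @return A matrix of class `dez_matrix`: genes x comparisons, comparison
#'   columns named `"a|b"`. Genes with zero variance across both clusters of a
#'   pair get z = 0.
#' @export
cluster_de_zscores <- function(expr, clustering, method = c("wilcoxon", "welch")) {
  method <- match.arg(method)
  assert_that(inherits(expr, "expression_matrix"), "`expr` must be an expression_matrix")
  clustering <- as.data.frame(clustering)
  assert_that(all(c("cell_id", "cluster") %in% names(clustering)),
              "`clustering` needs columns cell_id, cluster")
  lab <- setNames(as.character(clustering$cluster), as.character(clustering$cell_id))
  missing <- setdiff(expr$cell_ids, names(lab))
  assert_that(length(missing) == 0,
              sprintf("%d cells have no cluster label (e.g. %s)",
                      length(missing), missing[1]))
  labels <- lab[expr$cell_ids]
  clusters <- sort(unique(labels))
  assert_that(length(clusters) >= 2, "need at least 2 clusters")
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2]
  assert_that(length(small) == 0,
              sprintf("cluster '%s' has fewer than 2 cells", small[1]))

  m <- as.matrix(expr$values)
  pairs <- utils::combn(clusters, 2)
  zcols <- lapply(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    xa <- m[, labels == a, drop = FALSE]
    xb <- m[, labels == b, drop = FALSE]
    if (method == "wilcoxon") wilcox_z_rows(xa, xb) else welch_z_rows(xa, xb)
  })
  z <- do.call(cbind, zcols)
  dimnames(z) <- list(expr$gene_ids, paste(pairs[1, ], pairs[2, ], sep = "|"))
  class(z) <- c("dez_matrix", class(z))
  z
}

# Row-wise Wilcoxon rank-sum z with tie correction; sign positive when group
# a sits higher in the pooled ranking.
wilcox_z_rows <- function(xa, xb) {
  n1 <- ncol(xa); n2 <- ncol(xb); n <- n1 + n2
  x <- cbind(xa, xb)
  z <- apply(x, 1L, function(v) {
    r <- rank(v)
    w <- sum(r[seq_len(n1)])
    mu <- n1 * (n + 1) / 2
    ties <- table(v)
    tie_term <- sum(ties^3 - ties)
    sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sig2 <= 0) return(0)
    (w - mu) / sqrt(sig2)
  })
  unname(z)
}

welch_z_rows <- function(xa, xb) {
  m1 <- rowMeans(xa); m2 <- rowMeans(xb)
  v1 <- apply(xa, 1L, stats::var); v2 <- apply(xb, 1L, stats::var)
  se <- sqrt(v1 / ncol(xa) + v2 / ncol(xb))
  z <- (m1 - m2) / se
  z[!is.finite(z)] <- 0
  unname(z)
}

#' Gene-gene correlation of DE z-score profiles
#'
#' @param dez a `dez_matrix` from [cluster_de_zscores()] (or any genes x
#'   comparisons matrix with at least 3 columns).
#' @param method `"pearson"` or `"spearman"`.
#'
#' @return A symmetric genes x genes correlation matrix with unit diagonal.
#'   Genes whose z-profile is constant get correlation 0 to all other genes
#'   (their correlation is undefined; 0 encodes "no evidence").
#' @export
zscore_correlation <- function(dez, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  dez <- unclass(dez)
  assert_that(is.matrix(dez) && ncol(dez) >= 3,
              "need at least 3 comparison columns for a stable correlation")
  r <- suppressWarnings(stats::cor(t(dez), method = method))
  constant <- apply(dez, 1L, function(v) length(unique(v)) == 1L)
  r[constant, ] <- 0
  r[, constant] <- 0
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  dimnames(r) <- list(rownames(dez), rownames(dez))
  r
}

#' Threshold a correlation matrix into a co-expression network
#'
#' Retains the strongest gene-pair correlations as undirected weighted edges,
#' either the top `top_k` pairs or all pairs at or above a fixed `threshold`.
#' Ranking uses absolute correlation by default (captures co-repression);
#' ties at the cutoff are broken by lexicographic gene-pair order so the
#' result is deterministic.
#'
#' @param corr symmetric correlation matrix with gene dimnames.
#' @param top_k number of edges to retain (mutually exclusive with
#'   `threshold`).
#' @param threshold retain all pairs with ranking value >= threshold.
#' @param rank_by `"absolute"` or `"signed"`.
#' @param keep_isolated keep correlation-matrix genes without retained edges
#'   as isolated nodes (default TRUE).
#'
#' @return An undirected `igraph` ([gene_network()]) whose edge `weight` is
#'   the signed correlation.
#' @export
build_coexpression_network <- function(corr, top_k = NULL, threshold = NULL,
                                       rank_by = c("absolute", "signed"),
                                       keep_isolated = TRUE) {
  rank_by <- match.arg(rank_by)
  assert_that(is.matrix(corr) && nrow(corr) == ncol(corr), "`corr` must be square")
  genes <- rownames(corr)
  assert_that(!is.null(genes), "`corr` needs gene dimnames")
  assert_that(xor(is.null(top_k), is.null(threshold)),
              "supply exactly one of `top_k`, `threshold`")

  ut <- upper.tri(corr)
  idx <- which(ut, arr.ind = TRUE)
  val <- corr[ut]
  key <- if (rank_by == "absolute") abs(val) else val

  if (!is.null(top_k)) {
    top_k <- assert_count(top_k, "top_k", 1L)
    assert_that(top_k <= length(val), "`top_k` exceeds the number of gene pairs")
    ord <- order(-key, genes[idx[, 1]], genes[idx[, 2]])
    pick <- ord[seq_len(top_k)]
  } else {
    pick <- which(key >= threshold)
  }
  edges <- tibble::tibble(
    gene1 = genes[idx[pick, 1]],
    gene2 = genes[idx[pick, 2]],
    weight = val[pick]
  )
  gene_network(edges, nodes = if (keep_isolated) genes else NULL)
}
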