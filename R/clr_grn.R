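# Context-likelihood-of-relatedness (CLR) background correction and directed
# GRN construction.
#
# Each correlation R[i, j] is rescored against the distribution of gene i's
# row of R and gene j's column:
#   z_i = (R[i,j] - mean(row i)) / sd(row i)
#   z_j = (R[i,j] - mean(col j)) / sd(col j)
#   z(g_i, g_j) = sqrt(z_i^2 + z_j^2)
# The diagonal (self-correlation of 1) is excluded from every row/column mean
# and sd; including it would bias each background upward.

#' CLR background correction of a correlation matrix
#'
#' @param corr square symmetric correlation matrix with gene dimnames.
#' @param clamp_negative if TRUE, negative row/column z-scores are set to 0
#'   before squaring (the classic CLR convention); default FALSE keeps the
#'   plain quadrature combination.
#'
#' @return A symmetric non-negative matrix of CLR pseudo z-scores with zero
#'   diagonal. Rows (or columns) with zero standard deviation contribute a
#'   z of 0.
#' @export
#' @examples
#' r <- matrix(c(1, .9, .1, .9, 1, .5, .1, .5, 1), 3, 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' clr_correct(r)
clr_correct <- function(corr, clamp_negative = FALSE) {
  assert_that(is.matrix(corr) && nrow(corr) == ncol(corr),
              "`corr` must be a square matrix")
  n <- nrow(corr)
  assert_that(n >= 3, "need at least 3 genes")
  off <- corr
  diag(off) <- NA
  mu <- rowMeans(off, na.rm = TRUE)
  sdv <- apply(off, 1L, stats::sd, na.rm = TRUE)

  zi <- (corr - mu) / sdv                 # row-wise z of R[i, j]
  zi[sdv == 0, ] <- 0
  zi[!is.finite(zi)] <- 0
  # column z: for symmetric R the column background of j equals its row
  # background, so z_j(i, j) = t(zi)[i, j]
  zj <- t((t(corr) - mu) / sdv)
  zj[, sdv == 0] <- 0
  zj[!is.finite(zj)] <- 0
  if (clamp_negative) {
    zi <- pmax(zi, 0)
    zj <- pmax(zj, 0)
  }
  z <- sqrt(zi^2 + zj^2)
  diag(z) <- 0
  dimnames(z) <- dimnames(corr)
  z
}

#' Build a directed TF-to-target regulatory network from CLR scores
#'
#' Gene pairs with CLR pseudo z-score at or above `z_threshold` are kept, and
#' pairs in which neither gene is an annotated transcriptional regulator are
#' discarded as likely non-causal co-variation. A (TF, non-TF) pair yields one
#' edge TF -> target; a (TF, TF) pair yields both orientations (the CLR score
#' carries no direction). Nodes without an incident edge are omitted.
#'
#' @param clr matrix from [clr_correct()] (gene dimnames required).
#' @param tf_list character vector of TF gene ids (must be non-empty).
#' @param z_threshold minimum pseudo z-score for an edge.
#'
#' @return A directed `igraph` GRN with vertex attribute `is_tf` and edge
#'   attribute `confidence` (the pseudo z).
#' @export
build_grn <- function(clr, tf_list, z_threshold) {
  assert_that(is.matrix(clr) && nrow(clr) == ncol(clr), "`clr` must be square")
  genes <- rownames(clr)
  assert_that(!is.null(genes), "`clr` needs gene dimnames")
  tf_list <- intersect(as.character(tf_list), genes)
  assert_that(length(tf_list) > 0,
              "`tf_list` is empty (the network would be empty by construction)")

  ut <- upper.tri(clr)
  idx <- which(ut & clr >= z_threshold, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(grn_network(tibble::tibble(source = character(), target = character(),
                                      confidence = numeric()),
                       tf_ids = tf_list, nodes = character()))
  }
  g1 <- genes[idx[, 1]]
  g2 <- genes[idx[, 2]]
  conf <- clr[idx]
  is_tf1 <- g1 %in% tf_list
  is_tf2 <- g2 %in% tf_list
  keep <- is_tf1 | is_tf2

  src <- c(g1[keep & is_tf1], g2[keep & is_tf2])
  dst <- c(g2[keep & is_tf1], g1[keep & is_tf2])
  cc <- c(conf[keep & is_tf1], conf[keep & is_tf2])
  grn_network(tibble::tibble(source = src, target = dst, confidence = cc),
              tf_ids = tf_list, nodes = character())
}
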