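# Cell-type specificity scores (tau, per-type z/p) and active-subnetwork
# extraction: connected gene sets with unexpectedly high aggregated
# specificity, found by simulated annealing with a Monte-Carlo background
# correction.

#' Tau cell-type specificity index
#'
#' For each gene, per-type mean (log) expression x_i is normalized by its
#' maximum, and `tau = sum(1 - x_hat_i) / (N - 1)` over the N cell types.
#' Tau is 0 for ubiquitous expression and 1 for expression confined to a
#' single type. Genes with all-zero expression get tau = 0 by convention.
#'
#' @param expr an [expression_matrix()].
#' @param type_labels data frame with columns `cell_id`, `type` covering the
#'   cells of `expr`.
#' @param log_transform take log1p of expression before averaging (default
#'   TRUE; the index is intended for log-scale data).
#' @param tau_threshold flag genes as `specific` when tau exceeds this value
#'   (default 0.8).
#'
#' @return tibble of class `tau_profile`: `gene`, `tau`, `argmax_type`,
#'   `specific`, plus one `x_<type>` column of per-type mean log expression
#'   per cell type.
#' @export
#' @examples
#' m <- matrix(c(8, 0, 0, 2, 2, 2), 2, 3, byrow = TRUE,
#'             dimnames = list(c("gA", "gB"), c("c1", "c2", "c3")))
#' expr <- expression_matrix(m, species = "demo")
#' labs <- data.frame(cell_id = colnames(m), type = c("T1", "T2", "T3"))
#' tau(expr, labs)   # gA: tau = 1 (one type only); gB: tau = 0 (uniform)
tau <- function(expr, type_labels, log_transform = TRUE, tau_threshold = 0.8) {
  assert_that(inherits(expr, "expression_matrix"), "`expr` must be an expression_matrix")
  x_bar <- type_means(expr, type_labels, log_transform)
  types <- colnames(x_bar)
  assert_that(length(types) >= 2, "tau needs at least 2 cell types (N - 1 = 0)")

  mx <- apply(x_bar, 1L, max)
  xhat <- x_bar / ifelse(mx > 0, mx, 1)
  tau_val <- rowSums(1 - xhat) / (ncol(x_bar) - 1)
  tau_val[mx == 0] <- 0
  argmax <- types[max.col(x_bar, ties.method = "first")]
  argmax[mx == 0] <- NA_character_

  out <- tibble::tibble(
    gene = rownames(x_bar),
    tau = unname(tau_val),
    argmax_type = argmax,
    specific = unname(tau_val) > tau_threshold
  )
  xmeans <- x_bar
  colnames(xmeans) <- paste0("x_", types)
  out <- dplyr::bind_cols(out, tibble::as_tibble(xmeans))
  class(out) <- c("tau_profile", class(out))
  out
}

# genes x types matrix of mean (log1p) expression
type_means <- function(expr, type_labels, log_transform) {
  type_labels <- as.data.frame(type_labels)
  assert_that(all(c("cell_id", "type") %in% names(type_labels)),
              "`type_labels` needs columns cell_id, type")
  lab <- setNames(as.character(type_labels$type), as.character(type_labels$cell_id))
  missing <- setdiff(expr$cell_ids, names(lab))
  assert_that(length(missing) == 0,
              sprintf("%d cells have no type label", length(missing)))
  labels <- lab[expr$cell_ids]
  types <- sort(unique(labels))
  m <- expr$values
  if (log_transform) m <- log1p(m)
  x_bar <- vapply(types, function(t) {
    Matrix::rowMeans(m[, labels == t, drop = FALSE])
  }, numeric(nrow(m)))
  x_bar <- matrix(x_bar, nrow = nrow(m),
                  dimnames = list(expr$gene_ids, types))
  x_bar
}

#' Per-type specificity z-scores and p-values
#'
#' Per gene, each type's mean (log) expression is standardized against the
#' mean and sd across all types, and the z is converted to a one-sided
#' upper-tail normal p-value for specificity to that type. Genes with zero
#' across-type sd get z = 0, p = 1.
#'
#' @inheritParams tau
#'
#' @return tibble in long format: `gene`, `type`, `z`, `p_value`.
#' @export
type_specificity_z <- function(expr, type_labels, log_transform = TRUE) {
  x_bar <- type_means(expr, type_labels, log_transform)
  assert_that(ncol(x_bar) >= 3, "need at least 3 cell types for across-type sd")
  mu <- rowMeans(x_bar)
  sdv <- apply(x_bar, 1L, stats::sd)
  z <- (x_bar - mu) / sdv
  z[sdv == 0, ] <- 0
  p <- stats::pnorm(z, lower.tail = FALSE)
  p[sdv == 0, ] <- 1
  tibble::tibble(
    gene = rep(rownames(x_bar), times = ncol(x_bar)),
    type = rep(colnames(x_bar), each = nrow(x_bar)),
    z = as.vector(z),
    p_value = as.vector(p)
  )
}

#' Active-subnetwork extraction by simulated annealing
#'
#' Finds connected subnetworks whose member genes carry unexpectedly small
#' specificity p-values. Per-gene p-values are mapped to z-scores by the
#' upper-quantile transform `z = qnorm(1 - p)`; several p-value columns (e.g.
#' one per species) are combined by Stouffer's method. A candidate set A of k
#' genes scores `z_A = sum(z_g) / sqrt(k)`, corrected against random same-size
#' gene sets: `s_A = (z_A - mu_k) / sigma_k`, with mu_k and sigma_k estimated
#' once from `n_background` random k-sets for every k (a single permutation
#' cumulative-sum pass). The search toggles one gene at a time, keeping the
#' induced subgraph connected, under Metropolis acceptance with geometric
#' cooling; multiple seeded starts return the top non-overlapping results.
#'
#' @param net undirected `igraph`.
#' @param gene_p data frame with column `gene` plus one or more p-value
#'   columns in (0, 1]; genes of `net` missing from it get p = 1. p = 0 is an
#'   error (infinite z).
#' @param n_starts number of annealing restarts; the best non-overlapping
#'   results across starts are returned.
#' @param n_iter annealing iterations per start.
#' @param t0,cooling initial temperature and geometric cooling factor.
#' @param n_background random gene sets per size for the correction.
#' @param max_results maximum number of non-overlapping subnetworks returned.
#' @param seed integer seed.
#'
#' @return list of `subnetwork_result` objects (class on each: list with
#'   `genes`, `score_zA`, `corrected_score`, `connected`), sorted by
#'   decreasing corrected score.
#' @export
active_subnetwork <- function(net, gene_p, n_starts = 3, n_iter = 20000,
                              t0 = 1.0, cooling = 0.995, n_background = 1000,
                              max_results = 3, seed = 1) {
  assert_that(igraph::vcount(net) > 0, "network is empty")
  gene_p <- as.data.frame(gene_p)
  assert_that("gene" %in% names(gene_p), "`gene_p` needs a `gene` column")
  pcols <- setdiff(names(gene_p), "gene")
  assert_that(length(pcols) >= 1, "`gene_p` needs at least one p-value column")
  pm <- as.matrix(gene_p[pcols])
  assert_that(all(pm > 0 & pm <= 1), "p-values must lie in (0, 1]; p = 0 gives infinite z")

  genes <- igraph::V(net)$name
  n <- length(genes)
  # clip p away from 1 so the upper-quantile transform stays finite
  pm <- pmin(pm, 1 - 1e-12)
  zg <- stats::qnorm(1 - pm)              # per-column z
  z_comb <- rowSums(zg) / sqrt(ncol(zg))  # Stouffer across columns
  z <- setNames(rep(stats::qnorm(1e-12), n), genes)  # missing genes: p = 1
  hit <- match(gene_p$gene, genes)
  ok <- !is.na(hit)
  z[hit[ok]] <- z_comb[ok]

  adj <- igraph::as_adj_list(net, mode = "all")
  adj <- lapply(adj, as.integer)

  with_seed(seed, {
    # background: mu_k, sigma_k for all k from random permutations (cumsum trick)
    perms <- replicate(n_background, cumsum(sample(z)) / sqrt(seq_len(n)))
    mu_k <- rowMeans(perms)
    sd_k <- apply(perms, 1L, stats::sd)
    sd_k[sd_k == 0] <- 1e-12
    corrected <- function(sum_z, k) ((sum_z / sqrt(k)) - mu_k[k]) / sd_k[k]

    run_start <- function() {
      cur <- sample.int(n, 1L)            # current member indices
      sum_z <- z[cur]
      best <- list(set = cur, score = corrected(sum_z, 1L))
      temp <- t0
      for (it in seq_len(n_iter)) {
        k <- length(cur)
        grow <- k == 1L || runif(1) < 0.5
        if (grow) {
          frontier <- setdiff(unique(unlist(adj[cur])), cur)
          if (!length(frontier)) { temp <- temp * cooling; next }
          cand <- frontier[sample.int(length(frontier), 1L)]
          new_set <- c(cur, cand)
          new_sum <- sum_z + z[cand]
        } else {
          drop <- cur[sample.int(k, 1L)]
          new_set <- setdiff(cur, drop)
          if (!subset_connected(new_set, adj)) { temp <- temp * cooling; next }
          new_sum <- sum_z - z[drop]
        }
        new_score <- corrected(new_sum, length(new_set))
        old_score <- corrected(sum_z, k)
        if (new_score >= old_score || runif(1) < exp((new_score - old_score) / temp)) {
          cur <- new_set; sum_z <- new_sum
          if (new_score > best$score) best <- list(set = cur, score = new_score)
        }
        temp <- temp * cooling
      }
      best
    }

    results <- lapply(seq_len(n_starts), function(i) run_start())
    results <- results[order(vapply(results, `[[`, numeric(1), "score"),
                             decreasing = TRUE)]
    taken <- integer(0)
    out <- list()
    for (res in results) {
      if (length(intersect(res$set, taken))) next
      taken <- c(taken, res$set)
      k <- length(res$set)
      out[[length(out) + 1L]] <- structure(
        list(genes = genes[res$set],
             score_zA = sum(z[res$set]) / sqrt(k),
             corrected_score = res$score,
             connected = subset_connected(res$set, adj)),
        class = "subnetwork_result"
      )
      if (length(out) >= max_results) break
    }
    out
  })
}

# BFS connectivity of a node-index subset over an adjacency list
subset_connected <- function(set, adj) {
  if (length(set) <= 1L) return(TRUE)
  inset <- logical(length(adj))
  inset[set] <- TRUE
  seen <- logical(length(adj))
  queue <- set[1]
  seen[queue] <- TRUE
  count <- 1L
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    nb <- adj[[v]]
    nb <- nb[inset[nb] & !seen[nb]]
    if (length(nb)) {
      seen[nb] <- TRUE
      count <- count + length(nb)
      queue <- c(queue, nb)
    }
  }
  count == length(set)
}

#' @export
print.subnetwork_result <- function(x, ...) {
  cat(sprintf("<subnetwork_result> %d genes, z_A = %.2f, corrected = %.2f, connected = %s\n",
              length(x$genes), x$score_zA, x$corrected_score, x$connected))
  invisible(x)
}

#' @export
glance.subnetwork_result <- function(x, ...) {
  tibble::tibble(n_genes = length(x$genes), score_zA = x$score_zA,
                 corrected_score = x$corrected_score, connected = x$connected)
}
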