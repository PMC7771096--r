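# Cross-species network comparison: homolog restriction, conserved-edge
# permutation test, DiffK differential connectivity, tail selection, and
# enrichment validation.

#' Restrict two networks to one-to-one homologous genes
#'
#' Relabels both networks into a shared namespace (species-1 ids) and drops
#' nodes and edges outside the homolog map.
#'
#' @param netA,netB undirected `igraph` gene networks for species 1 and 2.
#' @param map data frame with columns `species1`, `species2`, one-to-one.
#'
#' @return list with elements `netA`, `netB` on the shared namespace.
#' @export
restrict_to_homologs <- function(netA, netB, map) {
  map <- as.data.frame(map)
  assert_that(all(c("species1", "species2") %in% names(map)),
              "`map` needs columns species1, species2")
  assert_that(!anyDuplicated(map$species1) && !anyDuplicated(map$species2),
              "homolog map must be one-to-one (duplicate ids found)")
  to1 <- setNames(as.character(map$species1), as.character(map$species2))

  restrict <- function(net, rename) {
    keep <- if (rename) igraph::V(net)$name %in% names(to1)
            else igraph::V(net)$name %in% map$species1
    g <- igraph::induced_subgraph(net, which(keep))
    if (rename) {
      g <- igraph::set_vertex_attr(g, "name", value = unname(to1[igraph::V(g)$name]))
    }
    g
  }
  list(netA = restrict(netA, rename = FALSE), netB = restrict(netB, rename = TRUE))
}

#' Permutation test for conserved edge overlap
#'
#' Counts edges shared by two networks on a common namespace and compares the
#' count with a null ensemble of Erdos-Renyi resampled networks having the
#' same node and edge counts (optionally a degree-preserving rewiring null).
#' The Monte-Carlo p-value is `(1 + #null >= observed) / (n_perm + 1)`.
#'
#' @param netA,netB undirected `igraph` networks sharing a node namespace.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param null `"erdos"` (edge resampling) or `"degree"` (degree-preserving
#'   double-edge-swap rewiring of both networks).
#'
#' @return An object of class `overlap_result` (list): `observed_overlap`,
#'   `null_mean`, `null_sd`, `p_value`, `n_permutations`, `null_model`.
#' @export
conserved_overlap_test <- function(netA, netB, n_perm = 100, seed = 1,
                                   null = c("erdos", "degree")) {
  null <- match.arg(null)
  n_perm <- assert_count(n_perm, "n_perm", 1L)
  nodes <- union(igraph::V(netA)$name, igraph::V(netB)$name)
  n <- length(nodes)
  eA <- igraph::as_edgelist(netA, names = TRUE)
  eB <- igraph::as_edgelist(netB, names = TRUE)
  ia <- matrix(match(eA, nodes), ncol = 2)
  ib <- matrix(match(eB, nodes), ncol = 2)
  keyA <- pair_index(ia[, 1], ia[, 2], n)
  keyB <- pair_index(ib[, 1], ib[, 2], n)
  observed <- length(intersect(keyA, keyB))
  npairs <- n * (n - 1) / 2

  null_counts <- with_seed(seed, {
    if (null == "erdos") {
      vapply(seq_len(n_perm), function(i) {
        a <- sample.int(npairs, length(keyA))
        b <- sample.int(npairs, length(keyB))
        length(intersect(a, b))
      }, integer(1))
    } else {
      vapply(seq_len(n_perm), function(i) {
        ra <- igraph::rewire(netA, igraph::keeping_degseq(niter = 10 * igraph::ecount(netA)))
        rb <- igraph::rewire(netB, igraph::keeping_degseq(niter = 10 * igraph::ecount(netB)))
        ea <- matrix(match(igraph::as_edgelist(ra, names = TRUE), nodes), ncol = 2)
        eb <- matrix(match(igraph::as_edgelist(rb, names = TRUE), nodes), ncol = 2)
        length(intersect(pair_index(ea[, 1], ea[, 2], n),
                         pair_index(eb[, 1], eb[, 2], n)))
      }, integer(1))
    }
  })
  structure(
    list(observed_overlap = observed,
         null_mean = mean(null_counts),
         null_sd = stats::sd(null_counts),
         p_value = (1 + sum(null_counts >= observed)) / (n_perm + 1),
         n_permutations = n_perm,
         null_model = null),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> observed = %d, null = %.1f +/- %.1f (%s), p = %.3g (n_perm = %d)\n",
              x$observed_overlap, x$null_mean, x$null_sd, x$null_model,
              x$p_value, x$n_permutations))
  invisible(x)
}

#' @export
glance.overlap_result <- function(x, ...) {
  tibble::tibble(observed_overlap = x$observed_overlap, null_mean = x$null_mean,
                 null_sd = x$null_sd, p_value = x$p_value,
                 n_permutations = x$n_permutations, null_model = x$null_model)
}

#' DiffK differential connectivity between two species' networks
#'
#' For each gene i, `DiffK_i = log(k1_i + 10) - log(k2_i + 10)` where k1, k2
#' are the gene's connectivities (degrees) in the two networks. A pseudo-count
#' of 10 damps the disproportionate fold changes of low-connectivity genes;
#' values near zero indicate conserved connectivity. Degrees are first
#' normalized for network size by rescaling each species' degrees to the
#' common (average) mean degree, so the pseudo-count retains its meaning
#' across networks of different density.
#'
#' @param netA,netB undirected `igraph` networks on a shared namespace; genes
#'   missing from one network count as degree 0.
#' @param pseudo_count added to every (normalized) degree; default 10.
#' @param log_base `10` (default) or `exp(1)`. Ranks and tail sets are
#'   base-invariant.
#' @param normalize rescale degrees to a common mean before the formula
#'   (default TRUE).
#'
#' @return A tibble of class `diffk_table`: `gene`, `k_species1`,
#'   `k_species2` (normalized degrees), `diffk`.
#' @export
diffk <- function(netA, netB, pseudo_count = 10, log_base = 10,
                  normalize = TRUE) {
  assert_that(igraph::ecount(netA) > 0 && igraph::ecount(netB) > 0,
              "both networks need at least one edge (normalization undefined)")
  genes <- union(igraph::V(netA)$name, igraph::V(netB)$name)
  deg <- function(net) {
    d <- setNames(rep(0, length(genes)), genes)
    dn <- igraph::degree(net)
    d[names(dn)] <- dn
    d
  }
  k1 <- deg(netA)
  k2 <- deg(netB)
  if (normalize) {
    target <- mean(c(mean(k1), mean(k2)))
    k1 <- k1 * target / mean(k1)
    k2 <- k2 * target / mean(k2)
  }
  d <- (log(k1 + pseudo_count) - log(k2 + pseudo_count)) / log(log_base)
  out <- tibble::tibble(gene = genes, k_species1 = unname(k1),
                        k_species2 = unname(k2), diffk = unname(d))
  class(out) <- c("diffk_table", class(out))
  out
}

#' Empirical-null p-values and FDR for DiffK values
#'
#' DiffK values are approximately normal; a normal null is fitted either from
#' the first two moments of all values (`"moments"`) or robustly from the
#' uncontaminated center (`"central_quantile"`: median location, IQR/1.349
#' scale), and two-sided p-values plus Benjamini-Hochberg FDR are appended.
#'
#' @param table a `diffk_table` from [diffk()] (>= 20 genes).
#' @param null_fit `"moments"` or `"central_quantile"`.
#'
#' @return The input tibble with columns `p_value` and `fdr` added.
#' @export
diffk_pvalues <- function(table, null_fit = c("moments", "central_quantile")) {
  null_fit <- match.arg(null_fit)
  assert_that(is.data.frame(table) && "diffk" %in% names(table),
              "`table` must be a diffk_table")
  x <- table$diffk
  assert_that(length(x) >= 20, "need at least 20 genes to fit a null")
  if (null_fit == "moments") {
    mu <- mean(x); sig <- stats::sd(x)
  } else {
    mu <- stats::median(x)
    sig <- stats::IQR(x) / (2 * stats::qnorm(0.75))
  }
  assert_that(is.finite(sig) && sig > 0, "DiffK values have zero variance")
  p <- 2 * stats::pnorm(-abs((x - mu) / sig))
  out <- dplyr::mutate(table, p_value = p, fdr = stats::p.adjust(p, "BH"))
  class(out) <- unique(c("diffk_table", class(out)))
  out
}

#' Select differential and conserved connectivity tails
#'
#' @param table a `diffk_table`.
#' @param top_frac,bottom_frac fractions for the two DiffK tails (genes more
#'   connected in species 1 / species 2).
#' @param conserved_frac fraction with the smallest `|DiffK|` (conserved
#'   connectivity).
#'
#' @return list of character vectors `top`, `bottom`, `conserved`; sizes are
#'   `floor(frac * N)`, ties broken by lexicographic gene id.
#' @export
select_tails <- function(table, top_frac = 0.05, bottom_frac = 0.05,
                         conserved_frac = 0.10) {
  assert_that(is.data.frame(table) && all(c("gene", "diffk") %in% names(table)),
              "`table` must be a diffk_table")
  n <- nrow(table)
  sizes <- floor(c(top_frac, bottom_frac, conserved_frac) * n)
  assert_that(all(sizes >= 1), "a fraction selects no genes at this table size")
  g <- table$gene
  d <- table$diffk
  top <- g[order(-d, g)][seq_len(sizes[1])]
  bottom <- g[order(d, g)][seq_len(sizes[2])]
  conserved <- g[order(abs(d), g)][seq_len(sizes[3])]
  list(top = top, bottom = bottom, conserved = conserved)
}

#' Odds-ratio enrichment curve of reference pairs among high correlations
#'
#' For each correlation cutoff c:
#' `OR(c) = (fraction of reference pairs with correlation > c) /
#'          (fraction of all unordered pairs with correlation > c)`.
#'
#' @param corr symmetric correlation matrix with gene dimnames.
#' @param reference_pairs data frame with two columns of gene ids (e.g.
#'   ChIP-derived TF-target pairs) within the matrix universe.
#' @param cutoffs numeric vector of correlation cutoffs.
#' @param use_absolute compare `|correlation|` to the cutoffs (default TRUE).
#'
#' @return tibble of class `or_curve`: `cutoff`, `n_reference`, `n_all`,
#'   `odds_ratio` (NA where no pair of either kind exceeds the cutoff).
#' @export
enrichment_odds_ratio <- function(corr, reference_pairs, cutoffs,
                                  use_absolute = TRUE) {
  genes <- rownames(corr)
  rp <- as.data.frame(reference_pairs)
  assert_that(ncol(rp) >= 2, "`reference_pairs` needs two gene columns")
  a <- as.character(rp[[1]]); b <- as.character(rp[[2]])
  keep <- a %in% genes & b %in% genes & a != b
  a <- a[keep]; b <- b[keep]
  assert_that(length(a) > 0, "no reference pair falls inside the gene universe")

  vals <- corr[upper.tri(corr)]
  ref_vals <- corr[cbind(match(a, genes), match(b, genes))]
  # deduplicate unordered reference pairs
  ref_vals <- ref_vals[!duplicated(edge_key(a, b))]
  if (use_absolute) {
    vals <- abs(vals); ref_vals <- abs(ref_vals)
  }
  purrr::map_dfr(cutoffs, function(cut) {
    fr <- mean(ref_vals > cut)
    fa <- mean(vals > cut)
    tibble::tibble(
      cutoff = cut,
      n_reference = sum(ref_vals > cut),
      n_all = sum(vals > cut),
      odds_ratio = if (fr == 0 || fa == 0) NA_real_ else fr / fa
    )
  })
}

#' Fisher gene-set enrichment
#'
#' One-sided Fisher exact enrichment of a query gene set against named
#' annotation sets over a fixed universe (the generic replacement for
#' ontology-database enrichment: annotation sets are plain gene lists, e.g.
#' read from GMT).
#'
#' @param query character vector, subset of `universe`.
#' @param universe character vector of all genes considered.
#' @param annotation_sets named list of character vectors.
#'
#' @return tibble: `set`, `set_size`, `query_size`, `overlap`, `expected`,
#'   `p_value`, `fdr`.
#' @export
gene_set_enrichment <- function(query, universe, annotation_sets) {
  universe <- unique(as.character(universe))
  assert_that(length(universe) > 0, "`universe` is empty")
  query <- unique(intersect(as.character(query), universe))
  assert_that(length(setdiff(query, universe)) == 0, "query must be within universe")
  assert_that(length(annotation_sets) > 0 && !is.null(names(annotation_sets)),
              "`annotation_sets` must be a named list")
  res <- purrr::imap_dfr(annotation_sets, function(set, nm) {
    set <- intersect(unique(as.character(set)), universe)
    ov <- length(intersect(query, set))
    tab <- matrix(c(ov,
                    length(query) - ov,
                    length(set) - ov,
                    length(universe) - length(query) - length(set) + ov),
                  nrow = 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    tibble::tibble(set = nm, set_size = length(set), query_size = length(query),
                   overlap = ov,
                   expected = length(query) * length(set) / length(universe),
                   p_value = p)
  })
  dplyr::mutate(res, fdr = stats::p.adjust(.data$p_value, "BH"))
}
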