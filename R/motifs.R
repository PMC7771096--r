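# Exact 3-/4-node motif census. Connected induced subgraphs are enumerated
# with the ESU algorithm, mapped to canonical ids (minimal row-major adjacency
# bitmask over all node relabelings, the mfinder dictionary convention), and
# compared against a degree-preserving rewiring null.

perm_cache <- new.env(parent = emptyenv())

perms_of <- function(k) {
  key <- as.character(k)
  if (is.null(perm_cache[[key]])) {
    pm <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
    pm <- pm[apply(pm, 1L, function(r) !anyDuplicated(r)), , drop = FALSE]
    perm_cache[[key]] <- pm
  }
  perm_cache[[key]]
}

adj_mask <- function(a) {
  # row-major bitmask: entry (i, j) -> bit (i-1)*k + (j-1)
  idx <- which(t(a) != 0)
  sum(2^(idx - 1))
}

#' Canonical motif id of a small directed subgraph
#'
#' The id is the minimum, over all k! node relabelings, of the row-major
#' adjacency bitmask `sum over edges (i, j) of 2^(i*k + j)` (0-based), the
#' convention of the mfinder motif dictionary. Isomorphic subgraphs share the
#' same id; e.g. the feed-forward loop has id 38 and the bi-fan id 204.
#'
#' @param adjacency k x k 0/1 matrix, k in \{3, 4\}, zero diagonal.
#'
#' @return integer canonical id.
#' @export
#' @examples
#' ffl <- matrix(0, 3, 3); ffl[1, 2] <- ffl[1, 3] <- ffl[2, 3] <- 1
#' canonical_motif_id(ffl)   # 38
canonical_motif_id <- function(adjacency) {
  a <- (as.matrix(adjacency) != 0) * 1L
  k <- nrow(a)
  assert_that(k %in% c(3L, 4L) && ncol(a) == k, "adjacency must be 3x3 or 4x4")
  assert_that(all(diag(a) == 0), "self-loops are not allowed")
  pm <- perms_of(k)
  min(apply(pm, 1L, function(p) adj_mask(a[p, p])))
}

# canonical ids memoised by raw mask (<= 2^16 distinct masks)
mask_cache <- new.env(parent = emptyenv())

canonical_from_matrix <- function(a, k) {
  raw <- adj_mask(a)
  key <- paste0(k, "_", raw)
  hit <- mask_cache[[key]]
  if (!is.null(hit)) return(hit)
  pm <- perms_of(k)
  val <- min(apply(pm, 1L, function(p) adj_mask(a[p, p])))
  mask_cache[[key]] <- val
  val
}

# ESU (Wernicke) enumeration of connected k-node induced subgraphs, each
# subset exactly once. `adj` = undirected adjacency list of integer ids.
esu_subsets <- function(adj, k) {
  out <- vector("list", 2048L)
  n_out <- 0L
  push <- function(sub) {
    n_out <<- n_out + 1L
    if (n_out > length(out)) length(out) <<- 2L * n_out
    out[[n_out]] <<- sub
  }
  extend <- function(sub, ext, v) {
    if (length(sub) == k) {
      push(sub)
      return()
    }
    nbhd_sub <- unique(unlist(adj[sub], use.names = FALSE))
    while (length(ext)) {
      w <- ext[1]
      ext <- ext[-1]
      nw <- adj[[w]]
      add <- nw[nw > v & !(nw %in% sub) & !(nw %in% nbhd_sub)]
      extend(c(sub, w), union(ext, add), v)
    }
  }
  for (v in seq_along(adj)) {
    ext0 <- adj[[v]][adj[[v]] > v]
    if (length(ext0) || k == 1L) extend(v, ext0, v)
  }
  out[seq_len(n_out)]
}

#' Census of connected 3- or 4-node induced subgraphs
#'
#' Enumerates every weakly-connected induced subgraph on `size` nodes exactly
#' once (ESU algorithm) and tallies counts per canonical motif id.
#'
#' @param grn simple directed `igraph`.
#' @param size 3 or 4.
#'
#' @return named integer vector: canonical id -> count.
#' @export
enumerate_subgraphs <- function(grn, size) {
  size <- assert_count(size, "size", 3L)
  assert_that(size %in% c(3L, 4L), "`size` must be 3 or 4")
  n <- igraph::vcount(grn)
  if (n < size) return(setNames(integer(0), character(0)))
  amat <- as.matrix(igraph::as_adjacency_matrix(grn, sparse = TRUE))
  amat <- (amat != 0) * 1L
  und <- amat | t(amat)
  adj <- lapply(seq_len(n), function(i) which(und[i, ]))
  subsets <- esu_subsets(adj, size)
  if (!length(subsets)) return(setNames(integer(0), character(0)))
  ids <- vapply(subsets, function(s) canonical_from_matrix(amat[s, s], size),
                numeric(1))
  tab <- table(ids)
  setNames(as.integer(tab), names(tab))
}

#' Degree-preserving rewiring of a directed network
#'
#' Randomizes edges by repeated double-edge swaps
#' `(a -> b, c -> d) => (a -> d, c -> b)`, rejecting swaps that would create
#' self-loops or duplicate edges. Every node's in- and out-degree is exactly
#' preserved.
#'
#' @param grn simple directed `igraph` with >= 2 edges.
#' @param swaps_per_edge attempted swaps per edge (default 10).
#' @param seed integer seed.
#'
#' @return A rewired `igraph` with identical vertex set and attributes. If no
#'   valid swap exists the input is returned unchanged with a warning.
#' @export
rewire_preserving_degrees <- function(grn, swaps_per_edge = 10, seed = 1) {
  m <- igraph::ecount(grn)
  assert_that(m >= 2, "need at least 2 edges to swap")
  el <- igraph::as_edgelist(grn, names = FALSE)
  n <- igraph::vcount(grn)
  with_seed(seed, {
    keys <- new.env(hash = TRUE, parent = emptyenv())
    kf <- function(a, b) paste(a, b)
    for (i in seq_len(m)) keys[[kf(el[i, 1], el[i, 2])]] <- TRUE
    accepted <- 0L
    for (it in seq_len(swaps_per_edge * m)) {
      e <- sample.int(m, 2L)
      a <- el[e[1], 1]; b <- el[e[1], 2]
      cc <- el[e[2], 1]; d <- el[e[2], 2]
      if (a == d || cc == b) next
      if (!is.null(keys[[kf(a, d)]]) || !is.null(keys[[kf(cc, b)]])) next
      rm(list = c(kf(a, b), kf(cc, d)), envir = keys)
      keys[[kf(a, d)]] <- TRUE
      keys[[kf(cc, b)]] <- TRUE
      el[e[1], 2] <- d
      el[e[2], 2] <- b
      accepted <- accepted + 1L
    }
    if (accepted == 0L) {
      rlang::warn("no valid double-edge swap found; returning the input unchanged")
      return(grn)
    }
    g <- igraph::make_empty_graph(n = n, directed = TRUE)
    for (at in igraph::vertex_attr_names(grn)) {
      g <- igraph::set_vertex_attr(g, at, value = igraph::vertex_attr(grn, at))
    }
    igraph::add_edges(g, t(el))
  })
}

#' Motif significance against a degree-preserving null
#'
#' Counts every connected 3- and/or 4-node subgraph class in the GRN and in
#' `n_random` degree-preserving rewirings, and flags motifs by the three
#' criteria: occurrence > 5, empirical p < 0.05, and z > 2, where
#' `z = (observed - null_mean) / null_sd` and
#' `p = (1 + #\{null >= observed\}) / (n_random + 1)`.
#'
#' @param grn simple directed `igraph`.
#' @param n_random number of rewired null networks (warning below 100;
#'   require >= 20 for sd stability).
#' @param seed integer seed.
#' @param sizes subgraph sizes to scan (subset of c(3, 4)).
#' @param swaps_per_edge passed to [rewire_preserving_degrees()].
#'
#' @return tibble of class `motif_catalog`: `id`, `size`, `observed_count`,
#'   `null_mean`, `null_sd`, `z_score`, `p_value`, `is_motif`. When null_sd is
#'   0, z is 0 if observed equals the null mean and a large sentinel (1e6)
#'   when it exceeds it.
#' @export
motif_significance <- function(grn, n_random = 1000, seed = 1, sizes = c(3, 4),
                               swaps_per_edge = 10) {
  n_random <- assert_count(n_random, "n_random", 20L)
  if (n_random < 100) rlang::warn("n_random < 100: null sd estimates are unstable")
  sizes <- as.integer(sizes)
  assert_that(all(sizes %in% c(3L, 4L)), "`sizes` must be within c(3, 4)")

  census <- function(g) {
    purrr::map(setNames(sizes, sizes), function(s) enumerate_subgraphs(g, s))
  }
  obs <- census(grn)
  null_counts <- lapply(seq_len(n_random), function(i) {
    census(rewire_preserving_degrees(grn, swaps_per_edge = swaps_per_edge,
                                     seed = seed + i))
  })

  purrr::map_dfr(as.character(sizes), function(s) {
    ids <- unique(c(names(obs[[s]]),
                    unlist(lapply(null_counts, function(nc) names(nc[[s]])))))
    if (!length(ids)) return(tibble::tibble())
    nullmat <- vapply(null_counts, function(nc) {
      v <- nc[[s]][ids]
      v[is.na(v)] <- 0L
      as.numeric(v)
    }, numeric(length(ids)))
    nullmat <- matrix(nullmat, nrow = length(ids))
    o <- as.numeric(obs[[s]][ids])
    o[is.na(o)] <- 0
    mu <- rowMeans(nullmat)
    sdv <- apply(nullmat, 1L, stats::sd)
    z <- ifelse(sdv > 0, (o - mu) / sdv,
                ifelse(o == mu, 0, ifelse(o > mu, 1e6, -1e6)))
    p <- (1 + rowSums(nullmat >= o)) / (n_random + 1)
    tibble::tibble(
      id = as.integer(ids), size = as.integer(s), observed_count = as.integer(o),
      null_mean = mu, null_sd = sdv, z_score = z, p_value = p,
      is_motif = o > 5 & p < 0.05 & z > 2
    )
  }) |>
    (\(x) { class(x) <- c("motif_catalog", class(x)); x })()
}
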