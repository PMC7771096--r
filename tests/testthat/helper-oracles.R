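# Independent brute-force oracles used to validate the package's algorithmic
# paths on small inputs. These deliberately share no code with the
# implementations they check.

# --- shortest-path betweenness by explicit BFS path counting ----------------

bf_distances <- function(adj, s) {
  n <- length(adj)
  dist <- rep(Inf, n)
  dist[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (u in adj[[v]]) {
        if (is.infinite(dist[u])) {
          dist[u] <- dist[v] + 1
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- unique(nxt)
  }
  dist
}

# number of shortest s->v paths for all v, by DP over BFS levels
bf_sigma <- function(adj, s, dist) {
  n <- length(adj)
  sigma <- rep(0, n)
  sigma[s] <- 1
  for (d in sort(unique(dist[is.finite(dist) & dist > 0]))) {
    for (v in which(dist == d)) {
      preds <- adj[[v]][dist[adj[[v]]] == d - 1]
      sigma[v] <- sum(sigma[preds])
    }
  }
  sigma
}

# unnormalized betweenness, each unordered pair counted once
bf_betweenness <- function(net) {
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  adj <- lapply(igraph::as_adj_list(net, mode = "all"), as.integer)
  bc <- rep(0, n)
  dmat <- t(vapply(seq_len(n), function(s) bf_distances(adj, s), numeric(n)))
  smat <- t(vapply(seq_len(n), function(s) bf_sigma(adj, s, dmat[s, ]), numeric(n)))
  for (s in seq_len(n - 1)) {
    for (t in seq((s + 1), n)) {
      if (!is.finite(dmat[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (dmat[s, v] + dmat[v, t] == dmat[s, t]) {
          bc[v] <- bc[v] + smat[s, v] * smat[t, v] / smat[s, t]
        }
      }
    }
  }
  setNames(bc, nodes)
}

# --- CLR by direct elementwise evaluation of the printed formulas -----------

bf_clr <- function(r, clamp = FALSE) {
  n <- nrow(r)
  z <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      row_i <- r[i, -i]
      col_j <- r[-j, j]
      zi <- if (sd(row_i) > 0) (r[i, j] - mean(row_i)) / sd(row_i) else 0
      zj <- if (sd(col_j) > 0) (r[i, j] - mean(col_j)) / sd(col_j) else 0
      if (clamp) {
        zi <- max(zi, 0)
        zj <- max(zj, 0)
      }
      z[i, j] <- sqrt(zi^2 + zj^2)
    }
  }
  dimnames(z) <- dimnames(r)
  z
}

# --- exhaustive motif census by subset iteration ----------------------------

bf_motif_census <- function(grn, size) {
  amat <- as.matrix(igraph::as_adjacency_matrix(grn))
  amat <- (amat != 0) * 1L
  und <- (amat | t(amat)) * 1L
  n <- nrow(amat)
  connected <- function(s) {
    reach <- s[1]
    repeat {
      nxt <- unique(c(reach, s[colSums(und[reach, s, drop = FALSE]) > 0]))
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    length(reach) == length(s)
  }
  counts <- integer(0)
  for (s in utils::combn(n, size, simplify = FALSE)) {
    if (!connected(s)) next
    id <- as.character(hemanet::canonical_motif_id(amat[s, s]))
    counts[id] <- (if (is.na(counts[id])) 0L else counts[id]) + 1L
  }
  counts
}

# --- exhaustive hierarchy optimum -------------------------------------------

bf_hierarchy_optimum <- function(grn, n_levels) {
  tfs <- igraph::V(grn)$name[igraph::V(grn)$is_tf]
  el <- igraph::as_edgelist(grn, names = TRUE)
  tt <- el[el[, 1] %in% tfs & el[, 2] %in% tfs, , drop = FALSE]
  src <- match(tt[, 1], tfs)
  dst <- match(tt[, 2], tfs)
  choices <- seq(2L, n_levels)
  grids <- rep(list(choices), length(tfs))
  best <- 0L
  for (row in seq_len(length(choices)^length(tfs))) {
    idx <- row - 1L
    lev <- integer(length(tfs))
    for (k in seq_along(tfs)) {
      lev[k] <- choices[(idx %% length(choices)) + 1L]
      idx <- idx %/% length(choices)
    }
    obj <- sum(lev[src] > lev[dst])
    if (obj > best) best <- obj
  }
  best
}

# --- small fixture builders -------------------------------------------------

toy_expression <- function(m, species = "toy") {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  hemanet::expression_matrix(m, species = species)
}

clique_ring <- function(n_cliques = 10, clique_size = 6) {
  edges <- NULL
  for (k in seq_len(n_cliques)) {
    members <- paste0("q", k, "_", seq_len(clique_size))
    pairs <- t(utils::combn(members, 2))
    edges <- rbind(edges, pairs)
  }
  for (k in seq_len(n_cliques)) {
    nxt <- if (k == n_cliques) 1 else k + 1
    edges <- rbind(edges, c(paste0("q", k, "_1"), paste0("q", nxt, "_2")))
  }
  hemanet::gene_network(data.frame(gene1 = edges[, 1], gene2 = edges[, 2]))
}

random_symmetric_corr <- function(n, seed) {
  withr::with_seed(seed, {
    r <- matrix(stats::runif(n * n, -1, 1), n, n)
    r <- (r + t(r)) / 2
    diag(r) <- 1
    dimnames(r) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
    r
  })
}

edge_key_test <- function(a, b) paste(pmin(a, b), pmax(a, b))

grn_tfs_test <- function(grn) {
  igraph::V(grn)$name[igraph::V(grn)$is_tf]
}
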