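# Network topology diagnostics: centralities, density, small-world odds
# against Erdos-Renyi ensembles, and the log-log degree-frequency regression
# used as a scale-free diagnostic.

#' Per-node centrality profile
#'
#' Degree, unnormalized shortest-path betweenness (each unordered node pair
#' counted once), local clustering coefficient (triangles over possible; 0 by
#' convention for degree < 2) and PageRank (damping 0.85).
#'
#' @param net undirected `igraph` network (non-empty).
#' @param normalize_betweenness divide betweenness by the number of node pairs
#'   excluding the focal node (default FALSE, raw counts).
#'
#' @return tibble: `gene`, `degree`, `betweenness`, `clustering_coefficient`,
#'   `pagerank`. PageRank sums to 1 over nodes.
#' @export
centrality_profile <- function(net, normalize_betweenness = FALSE) {
  assert_that(igraph::vcount(net) > 0, "network is empty")
  cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  cc[!is.finite(cc)] <- 0
  tibble::tibble(
    gene = igraph::V(net)$name,
    degree = unname(igraph::degree(net)),
    betweenness = unname(igraph::betweenness(net, directed = FALSE, weights = NA,
                                             normalized = normalize_betweenness)),
    clustering_coefficient = cc,
    pagerank = unname(igraph::page_rank(net, damping = 0.85, weights = NA)$vector)
  )
}

#' Network density
#'
#' Ratio of realized to possible edges, `2 * E / (n * (n - 1))`.
#'
#' @param net undirected `igraph` with at least 2 nodes.
#' @return density in \[0, 1\].
#' @export
network_density <- function(net) {
  n <- igraph::vcount(net)
  assert_that(n >= 2, "density needs at least 2 nodes")
  2 * igraph::ecount(net) / (n * (n - 1))
}

#' Average shortest path length on the largest component
#'
#' Mean geodesic distance over unordered node pairs within the largest
#' connected component (ties between equal-sized components broken by
#' lexicographically smallest member).
#'
#' @param net undirected `igraph` with at least one edge.
#' @return mean shortest path length (numeric).
#' @export
average_shortest_path <- function(net) {
  assert_that(igraph::ecount(net) > 0, "network has no edges")
  comp <- igraph::components(net)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    first_member <- vapply(best, function(k) {
      min(igraph::V(net)$name[comp$membership == k])
    }, character(1))
    best <- best[order(first_member)][1]
  }
  sub <- igraph::induced_subgraph(net, which(comp$membership == best))
  # hop-count distances: ignore any correlation weights on the edges
  igraph::mean_distance(sub, weights = NA, directed = FALSE)
}

mean_local_cc <- function(net) {
  cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  cc[!is.finite(cc)] <- 0
  mean(cc)
}

#' Small-world statistics against an Erdos-Renyi ensemble
#'
#' Compares the observed mean shortest path length L and mean local clustering
#' coefficient CC with `n_random` Erdos-Renyi graphs having the same node and
#' edge counts. A network is flagged small-world when paths stay comparable to
#' random (`L_ratio <= l_max`) while clustering far exceeds it
#' (`CC_ratio >= cc_min`).
#'
#' @param net undirected `igraph`.
#' @param n_random size of the null ensemble (>= 1).
#' @param seed integer seed.
#' @param l_max,cc_min small-world ratio thresholds (defaults 3 and 5).
#'
#' @return An object of class `small_world_result` (list): `L_obs`, `CC_obs`,
#'   `L_null_mean`, `L_null_sd`, `CC_null_mean`, `CC_null_sd`, `L_ratio`,
#'   `CC_ratio`, `is_small_world`, `n_random`.
#' @export
small_world_odds <- function(net, n_random = 20, seed = 1, l_max = 3,
                             cc_min = 5) {
  n_random <- assert_count(n_random, "n_random", 1L)
  n <- igraph::vcount(net)
  e <- igraph::ecount(net)
  assert_that(e > 0, "network has no edges")
  l_obs <- average_shortest_path(net)
  cc_obs <- mean_local_cc(net)
  nulls <- lapply(seq_len(n_random), function(i) {
    g <- generate_random_graph("erdos", n, e, directed = FALSE,
                               seed = seed + i - 1L)
    c(L = average_shortest_path(g), CC = mean_local_cc(g))
  })
  nulls <- do.call(rbind, nulls)
  l_mu <- mean(nulls[, "L"]); cc_mu <- mean(nulls[, "CC"])
  res <- list(
    L_obs = l_obs, CC_obs = cc_obs,
    L_null_mean = l_mu, L_null_sd = stats::sd(nulls[, "L"]),
    CC_null_mean = cc_mu, CC_null_sd = stats::sd(nulls[, "CC"]),
    L_ratio = l_obs / l_mu,
    CC_ratio = if (cc_mu > 0) cc_obs / cc_mu else Inf,
    n_random = n_random
  )
  res$is_small_world <- res$L_ratio <= l_max && res$CC_ratio >= cc_min
  structure(res, class = "small_world_result")
}

#' @export
print.small_world_result <- function(x, ...) {
  cat(sprintf("<small_world_result> L = %.3f (null %.3f, ratio %.2f); CC = %.3f (null %.4f, ratio %.2f); small-world: %s\n",
              x$L_obs, x$L_null_mean, x$L_ratio, x$CC_obs, x$CC_null_mean,
              x$CC_ratio, x$is_small_world))
  invisible(x)
}

#' @export
glance.small_world_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("L_obs", "CC_obs", "L_null_mean", "L_null_sd",
                                 "CC_null_mean", "CC_null_sd", "L_ratio",
                                 "CC_ratio", "is_small_world", "n_random")])
}

#' Log-log degree-frequency regression (scale-free diagnostic)
#'
#' Bins positive degrees into log-spaced bins, regresses log10 frequency
#' density on log10 degree and returns the slope and R-squared. A strongly
#' negative slope with high R-squared is the heavy-tail signature; this is a
#' diagnostic, not a formal power-law test.
#'
#' @param net undirected `igraph` (or a numeric degree vector) with at least 3
#'   distinct positive degree values.
#' @param n_bins number of log-spaced bins (default 12).
#'
#' @return An object of class `degree_fit` (list): `slope`, `r_squared`,
#'   `bins` (tibble: degree, frequency), `fit` (the `lm` object).
#' @export
degree_distribution_fit <- function(net, n_bins = 12) {
  deg <- if (is.numeric(net)) net else igraph::degree(net)
  deg <- deg[deg > 0]
  assert_that(length(unique(deg)) >= 3,
              "need at least 3 distinct positive degrees (degenerate distribution)")
  brks <- unique(10^seq(log10(min(deg)), log10(max(deg)), length.out = n_bins + 1))
  brks[length(brks)] <- brks[length(brks)] + 1e-9
  bin <- cut(deg, breaks = brks, include.lowest = TRUE, right = FALSE)
  counts <- table(bin)
  widths <- diff(brks)
  centers <- sqrt(brks[-length(brks)] * brks[-1])
  keep <- counts > 0
  dens <- as.numeric(counts[keep]) / widths[keep] / length(deg)
  x <- log10(centers[keep])
  y <- log10(dens)
  assert_that(length(x) >= 3, "too few occupied bins for a regression")
  fit <- stats::lm(y ~ x)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         r_squared = summary(fit)$r.squared,
         bins = tibble::tibble(degree = centers[keep], frequency = dens),
         fit = fit),
    class = "degree_fit"
  )
}

#' @export
print.degree_fit <- function(x, ...) {
  cat(sprintf("<degree_fit> slope = %.3f, R^2 = %.3f over %d log bins\n",
              x$slope, x$r_squared, nrow(x$bins)))
  invisible(x)
}

#' @export
glance.degree_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, r_squared = x$r_squared, n_bins = nrow(x$bins))
}
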