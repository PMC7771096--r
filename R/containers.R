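#' Expression matrix container
#'
#' A light wrapper around a genes x cells (sparse) count matrix carrying gene
#' ids, cell ids and a species tag. Values must be non-negative (UMI counts
#' or log-normalized expression).
#'
#' @param values genes x cells numeric matrix or `Matrix::sparseMatrix`.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param cell_ids character vector of unique cell identifiers (columns).
#' @param species single string tagging the species of origin.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `gene_ids`, `cell_ids`, `species`.
#' @export
#' @examples
#' m <- matrix(rpois(20, 2), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
#' expression_matrix(m, rownames(m), colnames(m), "human")
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values), species = "unknown") {
  assert_that(!is.null(gene_ids) && !is.null(cell_ids),
              "gene_ids and cell_ids are required (or set dimnames)")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  assert_that(nrow(values) == length(gene_ids) && ncol(values) == length(cell_ids),
              "ID lists must match matrix dimensions")
  assert_that(!anyDuplicated(gene_ids), "gene_ids must be unique")
  assert_that(!anyDuplicated(cell_ids), "cell_ids must be unique")
  assert_that(min(values) >= 0, "expression values must be non-negative")
  if (!methods::is(values, "CsparseMatrix")) {
    values <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE), "generalMatrix"),
                          "CsparseMatrix")
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(
    list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
         species = as.character(species)[1]),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d cells (species: %s)\n",
              length(x$gene_ids), length(x$cell_ids), x$species))
  cat(sprintf("  nonzero fraction: %.3f\n",
              Matrix::nnzero(x$values) / prod(dim(x$values))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Build an undirected gene co-expression network
#'
#' Constructs a simple undirected weighted graph from an edge table. Used both
#' as a user-facing constructor (e.g. for edge lists read from TSV) and
#' internally by [build_coexpression_network()].
#'
#' @param edges data frame with columns `gene1`, `gene2` and optionally
#'   `weight`.
#' @param nodes optional character vector of node ids; defaults to the genes
#'   present in `edges`. Extra ids become isolated nodes.
#'
#' @return An undirected `igraph` object with edge attribute `weight`.
#' @export
gene_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  assert_that(all(c("gene1", "gene2") %in% names(edges)),
              "edge table needs columns gene1, gene2")
  g1 <- as.character(edges$gene1)
  g2 <- as.character(edges$gene2)
  assert_that(!any(g1 == g2), "self-loops are not allowed in a gene network")
  nodes <- union(nodes %||% character(), union(g1, g2))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(edges)) {
    w <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else rep(1, nrow(edges))
    g <- igraph::add_edges(g, rbind(g1, g2), weight = w)
  }
  assert_that(!igraph::any_multiple(g), "duplicate edges are not allowed")
  g
}

#' Build a directed regulatory network (GRN)
#'
#' @param edges data frame with columns `source`, `target` and optionally
#'   `confidence`.
#' @param tf_ids character vector of transcription-factor ids; every edge
#'   source must be a TF.
#' @param nodes optional extra node ids.
#'
#' @return A directed `igraph` with vertex attribute `is_tf` and edge
#'   attribute `confidence`.
#' @export
grn_network <- function(edges, tf_ids, nodes = NULL) {
  edges <- as.data.frame(edges)
  assert_that(all(c("source", "target") %in% names(edges)),
              "edge table needs columns source, target")
  src <- as.character(edges$source)
  dst <- as.character(edges$target)
  assert_that(!any(src == dst), "self-loops are not allowed in a GRN")
  tf_ids <- as.character(tf_ids)
  assert_that(all(src %in% tf_ids), "every GRN edge source must be a TF")
  nodes <- union(nodes %||% character(), union(src, dst))
  g <- igraph::make_empty_graph(n = length(nodes), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  g <- igraph::set_vertex_attr(g, "is_tf", value = nodes %in% tf_ids)
  if (nrow(edges)) {
    conf <- if ("confidence" %in% names(edges)) as.numeric(edges$confidence) else rep(NA_real_, nrow(edges))
    g <- igraph::add_edges(g, rbind(src, dst), confidence = conf)
  }
  assert_that(!igraph::any_multiple(g), "duplicate edges are not allowed")
  g
}

#' Edge table of a network
#'
#' @param net an `igraph` network (directed or undirected).
#' @return A tibble with columns `gene1`/`gene2` (undirected) or
#'   `source`/`target` (directed) plus any edge attributes.
#' @export
as_edge_tibble <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  nm <- if (igraph::is_directed(net)) c("source", "target") else c("gene1", "gene2")
  out <- tibble::tibble(!!nm[1] := el[, 1], !!nm[2] := el[, 2])
  for (a in igraph::edge_attr_names(net)) out[[a]] <- igraph::edge_attr(net, a)
  out
}

grn_tfs <- function(grn) {
  igraph::V(grn)$name[igraph::V(grn)$is_tf %||% rep(FALSE, igraph::vcount(grn))]
}
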