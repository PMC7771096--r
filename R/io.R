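# Plain-text interchange: matrix-market triplet expression matrices with
# genes.tsv/cells.tsv sidecars, edge-list TSVs for networks, GMT gene sets,
# and two-column homolog maps.

#' Write an expression matrix as matrix-market triplets
#'
#' Writes `matrix.mtx` (genes x cells), `genes.tsv` (gene_id) and `cells.tsv`
#' (cell_id, species, and optional extra columns such as type labels).
#'
#' @param expr an [expression_matrix()].
#' @param dir output directory (created if needed).
#' @param cell_info optional data frame keyed by `cell_id` merged into
#'   cells.tsv.
#' @return `dir`, invisibly.
#' @export
write_expression_matrix <- function(expr, dir, cell_info = NULL) {
  assert_that(inherits(expr, "expression_matrix"), "`expr` must be an expression_matrix")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(expr$values, file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(gene_id = expr$gene_ids),
                   file.path(dir, "genes.tsv"))
  cells <- tibble::tibble(cell_id = expr$cell_ids, species = expr$species)
  if (!is.null(cell_info)) {
    cells <- dplyr::left_join(cells, as.data.frame(cell_info), by = "cell_id")
  }
  readr::write_tsv(cells, file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read an expression matrix written by [write_expression_matrix()]
#'
#' @param dir directory containing matrix.mtx, genes.tsv, cells.tsv.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"), show_col_types = FALSE)
  cells <- readr::read_tsv(file.path(dir, "cells.tsv"), show_col_types = FALSE)
  expression_matrix(m, genes$gene_id, cells$cell_id,
                    species = cells$species[1] %||% "unknown")
}

#' Write a network as an edge-list TSV
#'
#' Undirected networks get columns gene1, gene2, weight; directed GRNs get a
#' `#directed` header line and columns source, target, confidence.
#'
#' @param net an `igraph` network.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  tbl <- as_edge_tibble(net)
  if (igraph::is_directed(net)) {
    writeLines("#directed", path)
    readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(tbl, path)
  }
  invisible(path)
}

#' Read a network edge-list TSV
#'
#' Files starting with a `#directed` line are read as GRNs (requires `tf_ids`
#' unless a `source` column implies them); otherwise an undirected
#' [gene_network()] is returned.
#'
#' @param path edge-list TSV.
#' @param tf_ids TF ids for directed networks; defaults to the set of edge
#'   sources.
#' @return an `igraph` network.
#' @export
read_edge_list <- function(path, tf_ids = NULL) {
  first <- readLines(path, n = 1)
  directed <- identical(first, "#directed")
  tbl <- readr::read_tsv(path, skip = if (directed) 1 else 0,
                         show_col_types = FALSE)
  if (directed) {
    grn_network(tbl, tf_ids = tf_ids %||% unique(tbl$source))
  } else {
    gene_network(tbl)
  }
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (set name, description, genes, tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  assert_that(!is.null(names(sets)), "`sets` must be named")
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column homolog map TSV
#'
#' @param path TSV with columns species1, species2 (or any two columns, taken
#'   in order).
#' @return tibble with columns `species1`, `species2`.
#' @export
read_homolog_map <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  assert_that(ncol(tbl) >= 2, "homolog map needs two columns")
  out <- tibble::tibble(species1 = as.character(tbl[[1]]),
                        species2 = as.character(tbl[[2]]))
  assert_that(!anyDuplicated(out$species1) && !anyDuplicated(out$species2),
              "homolog map must be one-to-one")
  out
}
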