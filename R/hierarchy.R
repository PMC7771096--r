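# Regulatory hierarchy: TFs are assigned to levels 2..n_levels (non-TF
# targets sit at level 1) by simulated annealing that maximizes the number of
# TF-TF edges pointing from a higher level to a lower one. TF-to-target edges
# are downward by construction and invariant under the optimization.

#' Assign TFs to hierarchy levels by simulated annealing
#'
#' Maximizes the count of TF-TF edges (u, v) with level(u) > level(v). Moves
#' reassign one random TF to a random different level under Metropolis
#' acceptance with geometric cooling; several restarts are run and the best
#' assignment seen anywhere is returned.
#'
#' @param grn directed `igraph` GRN with vertex attribute `is_tf`.
#' @param n_levels total number of levels including the level-1 target tier
#'   (default 4); TFs occupy levels 2..n_levels.
#' @param n_iter moves per restart.
#' @param t0,cooling initial temperature and geometric cooling factor.
#' @param restarts number of annealing restarts.
#' @param seed integer seed.
#'
#' @return An object of class `hierarchy_assignment` (list): `levels` (tibble:
#'   gene, level, is_tf; targets at level 1), `n_levels`, `objective_value`
#'   (downward TF-TF edges), `n_tf_tf_edges`, `downward_fraction` (over all
#'   edges).
#' @export
assign_levels <- function(grn, n_levels = 4, n_iter = 20000, t0 = 1.0,
                          cooling = 0.995, restarts = 5, seed = 1) {
  n_levels <- assert_count(n_levels, "n_levels", 2L)
  tfs <- grn_tfs(grn)
  assert_that(length(tfs) > 0, "GRN has no TFs")
  el <- igraph::as_edgelist(grn, names = TRUE)
  tt <- el[el[, 1] %in% tfs & el[, 2] %in% tfs, , drop = FALSE]
  if (nrow(tt) == 0) {
    rlang::inform("GRN has no TF-TF edges; any level assignment is optimal")
  }
  src <- match(tt[, 1], tfs)
  dst <- match(tt[, 2], tfs)
  n_tf <- length(tfs)
  lv_choices <- seq(2L, n_levels)

  # per-TF incidence lists for O(deg) objective deltas
  inc_out <- split(seq_along(src), factor(src, levels = seq_len(n_tf)))
  inc_in <- split(seq_along(dst), factor(dst, levels = seq_len(n_tf)))

  best <- with_seed(seed, {
    global <- NULL
    for (r in seq_len(restarts)) {
      lev <- lv_choices[sample.int(length(lv_choices), n_tf, replace = TRUE)]
      down <- sum(lev[src] > lev[dst])
      cur_best <- list(lev = lev, obj = down)
      temp <- t0
      if (length(src) && length(lv_choices) >= 2) {
        for (it in seq_len(n_iter)) {
          tf <- sample.int(n_tf, 1L)
          cands <- lv_choices[lv_choices != lev[tf]]
          new_lv <- cands[sample.int(length(cands), 1L)]
          e_out <- inc_out[[tf]]
          e_in <- inc_in[[tf]]
          old_contrib <- sum(lev[tf] > lev[dst[e_out]]) + sum(lev[src[e_in]] > lev[tf])
          new_contrib <- sum(new_lv > lev[dst[e_out]]) + sum(lev[src[e_in]] > new_lv)
          delta <- new_contrib - old_contrib
          if (delta >= 0 || runif(1) < exp(delta / temp)) {
            lev[tf] <- new_lv
            down <- down + delta
            if (down > cur_best$obj) cur_best <- list(lev = lev, obj = down)
          }
          temp <- temp * cooling
        }
      }
      if (is.null(global) || cur_best$obj > global$obj) global <- cur_best
    }
    global
  })

  all_nodes <- igraph::V(grn)$name
  lvl <- setNames(rep(1L, length(all_nodes)), all_nodes)
  lvl[tfs] <- best$lev
  levels_tbl <- tibble::tibble(gene = all_nodes, level = unname(lvl),
                               is_tf = all_nodes %in% tfs)
  res <- structure(
    list(levels = levels_tbl, n_levels = n_levels,
         objective_value = best$obj, n_tf_tf_edges = nrow(tt)),
    class = "hierarchy_assignment"
  )
  res$downward_fraction <- downward_fraction(grn, res)
  res
}

#' @export
print.hierarchy_assignment <- function(x, ...) {
  cat(sprintf("<hierarchy_assignment> %d levels; %d/%d TF-TF edges downward; overall downward fraction %.3f\n",
              x$n_levels, x$objective_value, x$n_tf_tf_edges, x$downward_fraction))
  invisible(x)
}

#' @export
tidy.hierarchy_assignment <- function(x, ...) x$levels

#' @export
glance.hierarchy_assignment <- function(x, ...) {
  tibble::tibble(n_levels = x$n_levels, objective_value = x$objective_value,
                 n_tf_tf_edges = x$n_tf_tf_edges,
                 downward_fraction = x$downward_fraction)
}

#' Fraction of edges directed downward in a hierarchy
#'
#' Over all directed edges (TF-TF and TF-target), the fraction with
#' level(source) > level(target); non-TF targets sit at level 1.
#'
#' @param grn directed `igraph` GRN.
#' @param assignment a `hierarchy_assignment` or a data frame with columns
#'   `gene`, `level` covering every TF of `grn`.
#'
#' @return fraction in \[0, 1\].
#' @export
downward_fraction <- function(grn, assignment) {
  lv_tbl <- if (inherits(assignment, "hierarchy_assignment")) assignment$levels
            else as.data.frame(assignment)
  assert_that(all(c("gene", "level") %in% names(lv_tbl)),
              "`assignment` needs columns gene, level")
  lvl <- setNames(rep(1L, igraph::vcount(grn)), igraph::V(grn)$name)
  hit <- intersect(names(lvl), lv_tbl$gene)
  lvl[hit] <- lv_tbl$level[match(hit, lv_tbl$gene)]
  tfs <- grn_tfs(grn)
  unassigned <- setdiff(tfs, lv_tbl$gene)
  assert_that(length(unassigned) == 0,
              sprintf("TF '%s' has no level assignment", unassigned[1]))
  el <- igraph::as_edgelist(grn, names = TRUE)
  assert_that(nrow(el) > 0, "GRN has no edges")
  mean(lvl[el[, 1]] > lvl[el[, 2]])
}

#' TF collaboration scores
#'
#' For each TF, the fraction of its target genes that are co-targeted by at
#' least one other TF: `(# targets co-targeted by other TFs) / (# targets)`.
#' TFs without targets are omitted with a warning.
#'
#' @param grn directed `igraph` GRN.
#'
#' @return tibble: `tf`, `n_targets`, `n_cotargeted`, `collaboration_score`.
#' @export
collaboration_scores <- function(grn) {
  tfs <- grn_tfs(grn)
  assert_that(length(tfs) > 0, "GRN has no TFs")
  el <- igraph::as_edgelist(grn, names = TRUE)
  out_deg <- table(factor(el[, 1], levels = tfs))
  no_targets <- tfs[out_deg == 0]
  if (length(no_targets)) {
    rlang::warn(sprintf("%d TF(s) have no targets and are omitted (e.g. %s)",
                        length(no_targets), no_targets[1]))
  }
  # in a simple digraph, a target is co-targeted by another TF iff its
  # in-degree is at least 2
  in_deg <- table(el[, 2])
  cotarg <- in_deg[el[, 2]] >= 2
  tibble::tibble(tf = el[, 1], co = as.vector(cotarg)) |>
    dplyr::filter(.data$tf %in% tfs) |>
    dplyr::group_by(.data$tf) |>
    dplyr::summarise(n_targets = dplyr::n(),
                     n_cotargeted = sum(.data$co),
                     collaboration_score = mean(.data$co),
                     .groups = "drop")
}

#' Per-level summaries of a regulatory hierarchy
#'
#' For each hierarchy level: TF count, mean collaboration score, fraction of
#' member genes in each annotation set, mean degree in an optional external
#' interaction network, and mean tau specificity.
#'
#' @param assignment a `hierarchy_assignment` from [assign_levels()].
#' @param grn the GRN the assignment was computed on.
#' @param annotations optional named list of gene sets (e.g. essential genes,
#'   disease genes); genes outside the GRN are ignored with a warning.
#' @param interaction_net optional undirected `igraph` (e.g. protein
#'   interactions).
#' @param tau_profile optional [tau()] output.
#' @param tf_only restrict level membership to TFs (default TRUE; FALSE also
#'   counts level-1 targets).
#'
#' @return tibble with one row per level.
#' @export
level_summaries <- function(assignment, grn, annotations = NULL,
                            interaction_net = NULL, tau_profile = NULL,
                            tf_only = TRUE) {
  assert_that(inherits(assignment, "hierarchy_assignment"),
              "`assignment` must come from assign_levels()")
  lv <- assignment$levels
  if (tf_only) lv <- dplyr::filter(lv, .data$is_tf)
  collab <- collaboration_scores(grn)

  per_level <- lv |>
    dplyr::left_join(collab, by = c(gene = "tf")) |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      mean_collaboration = mean(.data$collaboration_score, na.rm = TRUE),
      .groups = "drop"
    )

  if (!is.null(annotations)) {
    universe <- igraph::V(grn)$name
    for (nm in names(annotations)) {
      set <- as.character(annotations[[nm]])
      outside <- setdiff(set, universe)
      if (length(outside)) {
        rlang::warn(sprintf("annotation '%s': %d gene(s) outside the GRN ignored",
                            nm, length(outside)))
      }
      frac <- vapply(per_level$level, function(l) {
        members <- lv$gene[lv$level == l]
        mean(members %in% set)
      }, numeric(1))
      per_level[[paste0("frac_", nm)]] <- frac
    }
  }
  if (!is.null(interaction_net)) {
    dn <- igraph::degree(interaction_net)
    per_level$mean_interaction_degree <- vapply(per_level$level, function(l) {
      members <- lv$gene[lv$level == l]
      mean(dn[intersect(members, names(dn))])
    }, numeric(1))
  }
  if (!is.null(tau_profile)) {
    tp <- setNames(tau_profile$tau, tau_profile$gene)
    per_level$mean_tau <- vapply(per_level$level, function(l) {
      members <- lv$gene[lv$level == l]
      mean(tp[intersect(members, names(tp))])
    }, numeric(1))
  }
  per_level
}
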