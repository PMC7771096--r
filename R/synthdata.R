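# Synthetic data generators: paired-species UMI matrices with planted
# co-expression modules and cell-type programs, planted hierarchical GRNs,
# and reference random graphs. All generators are pure functions of
# (config, seed).

#' Configuration for a synthetic species pair
#'
#' Parameters of the two-species single-cell count simulator. Counts follow a
#' negative binomial with a log-link on baseline + cell-type effect + module
#' latent factor; dropout is independent Bernoulli zero-masking. A fraction
#' `cross_species_rewire_frac` of module gene memberships is scrambled in
#' species 2, creating a known conserved/divergent split.
#'
#' @param n_genes number of homologous genes simulated per species.
#' @param n_cells_per_species cells per species.
#' @param n_types number of discrete cell types (>= 2).
#' @param n_tfs number of genes flagged as transcription factors
#'   (`n_tfs <= n_genes`).
#' @param module_count,module_size number and size of planted co-expressed
#'   modules (disjoint; `module_size >= 2`).
#' @param cross_species_rewire_frac fraction in \[0,1\] of module genes whose
#'   module membership is re-drawn in species 2.
#' @param dropout_rate Bernoulli zero-masking probability in \[0,1\].
#' @param nb_dispersion negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param type_effect,module_effect log-scale effect sizes of the cell-type
#'   program and the module latent factor.
#' @param baseline_mean mean baseline expression (counts per cell).
#' @param seed integer seed; identical seeds give byte-identical output.
#'
#' @return A list of class `species_pair_config`.
#' @export
species_pair_config <- function(n_genes = 500, n_cells_per_species = 1000,
                                n_types = 5, n_tfs = 50,
                                module_count = 10, module_size = 10,
                                cross_species_rewire_frac = 0.2,
                                dropout_rate = 0.3, nb_dispersion = 2,
                                type_effect = log(4), module_effect = 1,
                                baseline_mean = 0.5, seed = 1) {
  cfg <- list(
    n_genes = assert_count(n_genes, "n_genes", 2L),
    n_cells_per_species = assert_count(n_cells_per_species, "n_cells_per_species", 4L),
    n_types = assert_count(n_types, "n_types", 2L),
    n_tfs = assert_count(n_tfs, "n_tfs", 1L),
    module_count = assert_count(module_count, "module_count", 1L),
    module_size = assert_count(module_size, "module_size", 2L),
    cross_species_rewire_frac = assert_fraction(cross_species_rewire_frac,
                                                "cross_species_rewire_frac"),
    dropout_rate = assert_fraction(dropout_rate, "dropout_rate"),
    nb_dispersion = as.numeric(nb_dispersion),
    type_effect = as.numeric(type_effect),
    module_effect = as.numeric(module_effect),
    baseline_mean = as.numeric(baseline_mean),
    seed = assert_count(seed, "seed", 0L)
  )
  assert_that(cfg$nb_dispersion > 0, "`nb_dispersion` must be positive")
  assert_that(cfg$n_tfs <= cfg$n_genes, "`n_tfs` must not exceed `n_genes`")
  assert_that(cfg$module_count * cfg$module_size <= cfg$n_genes,
              "modules must fit inside the gene universe")
  structure(cfg, class = "species_pair_config")
}

#' Generate a paired-species synthetic expression data set
#'
#' Simulates two species' gene-by-cell UMI count matrices over a shared set of
#' one-to-one homologous genes, with discrete cell types, planted co-expressed
#' gene modules driven by a shared latent activity factor, planted TF-to-target
#' regulatory edges (TF modules regulate their member genes), overdispersed
#' negative-binomial counts and Bernoulli dropout.
#'
#' Module genes share a per-(module, type) latent activity plus per-cell noise,
#' so their cluster-pair DE z-score profiles correlate. In species 2 a fraction
#' `cross_species_rewire_frac` of module genes is reassigned to a different
#' module, so their network connectivity diverges across species.
#'
#' @param config a [species_pair_config()].
#'
#' @return A list with elements:
#'   \describe{
#'     \item{species1, species2}{[expression_matrix()] objects.}
#'     \item{homolog_map}{tibble with columns `species1`, `species2`.}
#'     \item{truth}{list with `module_membership` (tibble: gene, species1
#'       module, species2 module, scrambled flag), `planted_edges` (tibble:
#'       source, target), `type_of_cell` (tibble: cell_id, species, type),
#'       `type_specific_genes` (named list of gene vectors), `tf_ids`.}
#'   }
#' @export
#' @examples
#' sim <- generate_species_pair(species_pair_config(n_genes = 60,
#'   n_cells_per_species = 80, n_types = 3, module_count = 3,
#'   module_size = 5, seed = 42))
#' dim(sim$species1)
generate_species_pair <- function(config) {
  assert_that(inherits(config, "species_pair_config"),
              "`config` must be a species_pair_config")
  with_seed(config$seed, generate_species_pair_impl(config))
}

generate_species_pair_impl <- function(cfg) {
  ng <- cfg$n_genes
  nc <- cfg$n_cells_per_species
  nt <- cfg$n_types

  gene_base <- sprintf("g%04d", seq_len(ng))
  genes1 <- paste0(gene_base, "_s1")
  genes2 <- paste0(gene_base, "_s2")
  tf_idx <- seq_len(cfg$n_tfs)

  # disjoint planted modules, TFs preferentially seeded one per module so
  # planted regulatory edges exist (first member regulates the others)
  mod_genes <- seq_len(cfg$module_count * cfg$module_size)
  membership1 <- rep(NA_integer_, ng)
  membership1[mod_genes] <- rep(seq_len(cfg$module_count), each = cfg$module_size)

  # species 2: a fraction of module genes lose their module membership
  # (drop out of the shared co-expression program), so their network
  # connectivity diverges -- the split DiffK is designed to detect
  membership2 <- membership1
  n_scramble <- round(cfg$cross_species_rewire_frac * length(mod_genes))
  scrambled <- integer(0)
  if (n_scramble > 0) {
    scrambled <- sort(sample(mod_genes, n_scramble))
    membership2[scrambled] <- NA_integer_
  }

  # per-type specific gene programs (disjoint, drawn outside modules if room)
  prog_size <- max(2L, ng %/% (4L * nt))
  pool <- setdiff(seq_len(ng), mod_genes)
  if (length(pool) < prog_size * nt) pool <- seq_len(ng)
  prog_idx <- sample(pool, min(prog_size * nt, length(pool)))
  type_names <- paste0("T", seq_len(nt))
  type_prog <- split(prog_idx, rep(type_names, length.out = length(prog_idx)))

  baseline <- cfg$baseline_mean * exp(rnorm(ng, 0, 0.5))

  simulate_species <- function(membership, species, genes, cell_prefix) {
    types <- sample(rep(type_names, length.out = nc))
    # latent module activity: per-(module, type) mean + per-cell noise
    mod_type <- matrix(rnorm(cfg$module_count * nt), cfg$module_count, nt,
                       dimnames = list(NULL, type_names))
    mod_cell <- mod_type[, types, drop = FALSE] +
      matrix(rnorm(cfg$module_count * nc, 0, 0.3), cfg$module_count, nc)

    log_mu <- matrix(log(baseline), ng, nc)
    for (t in type_names) {
      idx <- type_prog[[t]]
      log_mu[idx, types == t] <- log_mu[idx, types == t] + cfg$type_effect
    }
    in_mod <- which(!is.na(membership))
    if (length(in_mod)) {
      log_mu[in_mod, ] <- log_mu[in_mod, ] +
        cfg$module_effect * mod_cell[membership[in_mod], , drop = FALSE]
    }
    mu <- exp(log_mu)
    counts <- matrix(rnbinom(ng * nc, size = cfg$nb_dispersion, mu = mu), ng, nc)
    if (cfg$dropout_rate > 0) {
      keep <- matrix(rbinom(ng * nc, 1L, 1 - cfg$dropout_rate), ng, nc)
      counts <- counts * keep
    }
    cells <- sprintf("%s%05d", cell_prefix, seq_len(nc))
    list(
      expr = expression_matrix(counts, genes, cells, species),
      types = tibble::tibble(cell_id = cells, species = species, type = types)
    )
  }

  s1 <- simulate_species(membership1, "species1", genes1, "c1_")
  s2 <- simulate_species(membership2, "species2", genes2, "c2_")

  # planted regulatory edges: the first (TF-designated) member of each module
  # regulates the other members; expressed in species1 ids
  planted <- purrr::map_dfr(seq_len(cfg$module_count), function(m) {
    members <- which(membership1 == m)
    tibble::tibble(source = genes1[members[1]], target = genes1[members[-1]])
  })
  tf_ids <- unique(c(genes1[tf_idx],
                     vapply(split(which(!is.na(membership1)), membership1[!is.na(membership1)]),
                            function(ix) genes1[min(ix)], character(1))))

  list(
    species1 = s1$expr,
    species2 = s2$expr,
    homolog_map = tibble::tibble(species1 = genes1, species2 = genes2),
    truth = list(
      module_membership = tibble::tibble(
        gene = genes1,
        module_species1 = membership1,
        module_species2 = membership2,
        scrambled = seq_len(ng) %in% scrambled
      ),
      planted_edges = planted,
      type_of_cell = dplyr::bind_rows(s1$types, s2$types),
      type_specific_genes = lapply(type_prog, function(ix) genes1[ix]),
      tf_ids = tf_ids,
      gene_baseline = setNames(baseline, genes1)
    ),
    config = cfg
  )
}

#' Generate a GRN with a planted level hierarchy
#'
#' Builds a directed TF-to-target network in which TFs occupy `n_levels` true
#' levels and a proportion `downward_frac` of TF-TF edges points from a higher
#' level to a lower one (the remainder point upward or laterally). Each target
#' gene receives `edges_per_node` incoming edges from random TFs; those edges
#' are downward by construction. The graph is simple with no self-loops.
#'
#' @param n_tf,n_target numbers of TFs and target genes.
#' @param n_levels total number of hierarchy levels including the level-1
#'   target tier; TFs occupy levels `2..n_levels` (>= 2).
#' @param downward_frac probability that a TF-TF edge is planted downward.
#' @param edges_per_node TF-TF edges per TF and incoming edges per target.
#' @param seed integer seed.
#'
#' @return list with `grn` (directed igraph, vertex attr `is_tf`, edge attr
#'   `confidence` = 1) and `true_levels` (tibble: gene, level; targets level 1,
#'   TF levels 2..n_levels).
#' @export
generate_planted_grn <- function(n_tf, n_target, n_levels = 4,
                                 downward_frac = 0.9, edges_per_node = 2,
                                 seed = 1) {
  n_tf <- assert_count(n_tf, "n_tf", 2L)
  n_target <- assert_count(n_target, "n_target", 0L)
  n_levels <- assert_count(n_levels, "n_levels", 2L)
  downward_frac <- assert_fraction(downward_frac, "downward_frac")
  edges_per_node <- assert_count(edges_per_node, "edges_per_node", 1L)

  with_seed(seed, {
    tfs <- sprintf("TF%03d", seq_len(n_tf))
    tgs <- if (n_target > 0) sprintf("TG%04d", seq_len(n_target)) else character()
    # TF levels 2..n_levels; targets sit below at level 1. Levels are
    # bottom-heavy (each level half the size of the one below), the pyramid
    # shape regulatory hierarchies show empirically.
    lv_seq <- seq(2L, n_levels)
    tf_level <- sample(lv_seq, n_tf, replace = TRUE,
                       prob = 2^(n_levels - lv_seq))
    names(tf_level) <- tfs

    n_tt <- n_tf * edges_per_node
    seen <- new.env(hash = TRUE)
    src <- character(n_tt); dst <- character(n_tt)
    k <- 0L; attempts <- 0L
    while (k < n_tt && attempts < 200L * n_tt) {
      attempts <- attempts + 1L
      down <- runif(1) < downward_frac
      u <- sample(tfs, 1L)
      cand <- if (down) tfs[tf_level < tf_level[[u]]] else tfs[tf_level >= tf_level[[u]]]
      cand <- setdiff(cand, u)
      if (!length(cand)) next
      v <- sample(cand, 1L)
      key <- paste(u, v)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      k <- k + 1L
      src[k] <- u; dst[k] <- v
    }
    src <- src[seq_len(k)]; dst <- dst[seq_len(k)]

    if (n_target > 0) {
      t_src <- as.vector(vapply(tgs, function(tg) sample(tfs, edges_per_node),
                                character(edges_per_node)))
      t_dst <- rep(tgs, each = edges_per_node)
      src <- c(src, t_src); dst <- c(dst, t_dst)
    }
    edges <- tibble::tibble(source = src, target = dst, confidence = 1)
    edges <- dplyr::distinct(edges)
    grn <- grn_network(edges, tf_ids = tfs, nodes = c(tfs, tgs))
    true_levels <- tibble::tibble(
      gene = c(tfs, tgs),
      level = c(unname(tf_level), rep(1L, length(tgs)))
    )
    list(grn = grn, true_levels = true_levels)
  })
}

#' Generate a reference random graph
#'
#' Erdos-Renyi G(n, m) graphs (a uniform sample of exactly `n_edges` distinct
#' node pairs) and Barabasi-Albert preferential-attachment graphs, used as
#' null ensembles for small-world and motif statistics.
#'
#' @param model `"erdos"` or `"barabasi"`.
#' @param n_nodes number of nodes.
#' @param n_edges_or_m number of edges (erdos) or edges added per new node
#'   (barabasi).
#' @param directed logical; directed graphs are supported for `"erdos"`.
#' @param seed integer seed.
#'
#' @return An `igraph` object with node names `n1..n_nodes`.
#' @export
generate_random_graph <- function(model = c("erdos", "barabasi"), n_nodes,
                                  n_edges_or_m, directed = FALSE, seed = 1) {
  model <- match.arg(model)
  n_nodes <- assert_count(n_nodes, "n_nodes", 2L)
  n_edges_or_m <- assert_count(n_edges_or_m, "n_edges_or_m", 0L)
  with_seed(seed, {
    g <- if (model == "erdos") {
      max_e <- if (directed) n_nodes * (n_nodes - 1) else n_nodes * (n_nodes - 1) / 2
      assert_that(n_edges_or_m <= max_e,
                  "infeasible edge count for a simple graph")
      igraph::sample_gnm(n_nodes, n_edges_or_m, directed = directed)
    } else {
      igraph::sample_pa(n_nodes, m = n_edges_or_m, directed = directed)
    }
    igraph::set_vertex_attr(g, "name", value = paste0("n", seq_len(n_nodes)))
  })
}
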