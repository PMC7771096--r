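# End-to-end orchestration: simulate -> co-expression -> CLR/GRN ->
# cross-species comparison -> topology -> specificity -> hierarchy -> motifs,
# with a JSON run manifest recording the config, seeds and output digests.

#' Pipeline configuration
#'
#' Collects per-stage parameters for [run_pipeline()]. Defaults run a small
#' but complete two-species synthetic analysis.
#'
#' @param simulate a [species_pair_config()].
#' @param top_k number of co-expression edges retained per species.
#' @param grn_thresholds CLR pseudo z-score thresholds; one GRN is written per
#'   threshold (edge counts are non-increasing in the threshold).
#' @param n_perm permutations for the conserved-overlap test.
#' @param n_random_smallworld null graphs for small-world ratios.
#' @param n_random_motifs rewired nulls for the motif scan.
#' @param motif_sizes subgraph sizes scanned (subset of c(3, 4)).
#' @param hierarchy_levels total hierarchy levels (incl. the target tier).
#' @param seed master seed; stage sub-seeds derive from it deterministically.
#'
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = species_pair_config(),
                            top_k = 2000,
                            grn_thresholds = c(3, 5),
                            n_perm = 50,
                            n_random_smallworld = 10,
                            n_random_motifs = 100,
                            motif_sizes = 3,
                            hierarchy_levels = 4,
                            seed = 1) {
  assert_that(inherits(simulate, "species_pair_config"),
              "`simulate` must be a species_pair_config")
  structure(
    list(simulate = simulate, top_k = assert_count(top_k, "top_k"),
         grn_thresholds = sort(as.numeric(grn_thresholds)),
         n_perm = assert_count(n_perm, "n_perm"),
         n_random_smallworld = assert_count(n_random_smallworld, "n_random_smallworld"),
         n_random_motifs = assert_count(n_random_motifs, "n_random_motifs", 20L),
         motif_sizes = as.integer(motif_sizes),
         hierarchy_levels = assert_count(hierarchy_levels, "hierarchy_levels", 2L),
         seed = assert_count(seed, "seed", 0L)),
    class = "pipeline_config"
  )
}

#' Run the full synthetic two-species network analysis
#'
#' Executes all stages in dependency order, writing each stage's outputs under
#' `out_dir` and returning a run manifest (also written as `manifest.json`)
#' listing the config, the seeds used and an md5 digest of every output file.
#' Rerunning with the same config reproduces the digests of all deterministic
#' stages.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param dry_run validate the configuration and report the stage plan without
#'   computing (default FALSE).
#'
#' @return list of class `run_manifest` (invisibly contains all in-memory
#'   stage results under `$results` unless `dry_run`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, dry_run = FALSE) {
  assert_that(inherits(config, "pipeline_config"), "`config` must be a pipeline_config")
  stages <- c("simulate", "coexpression", "grn", "compare", "topology",
              "specificity", "hierarchy", "motifs")
  if (dry_run) {
    return(structure(list(config = config, stages = stages, dry_run = TRUE),
                     class = "run_manifest"))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()

  # -- simulate ---------------------------------------------------------
  sim <- generate_species_pair(config$simulate)
  res$sim <- sim
  types1 <- dplyr::filter(sim$truth$type_of_cell, .data$species == "species1")
  types2 <- dplyr::filter(sim$truth$type_of_cell, .data$species == "species2")
  write_expression_matrix(sim$species1, file.path(out_dir, "species1"),
                          cell_info = types1[c("cell_id", "type")])
  write_expression_matrix(sim$species2, file.path(out_dir, "species2"),
                          cell_info = types2[c("cell_id", "type")])
  readr::write_tsv(sim$homolog_map, file.path(out_dir, "homolog_map.tsv"))
  readr::write_tsv(sim$truth$module_membership, file.path(out_dir, "truth_modules.tsv"))
  readr::write_tsv(sim$truth$planted_edges, file.path(out_dir, "truth_edges.tsv"))

  # -- co-expression per species ---------------------------------------
  nets <- list()
  corrs <- list()
  for (sp in c("species1", "species2")) {
    expr <- sim[[sp]]
    labs <- dplyr::filter(sim$truth$type_of_cell, .data$species == sp)
    dez <- cluster_de_zscores(expr, data.frame(cell_id = labs$cell_id,
                                               cluster = labs$type))
    corr <- zscore_correlation(dez)
    net <- build_coexpression_network(corr, top_k = config$top_k)
    write_edge_list(net, file.path(out_dir, paste0("coexpr_", sp, ".tsv")))
    nets[[sp]] <- net
    corrs[[sp]] <- corr
  }
  res$networks <- nets

  # -- GRN (species 1) --------------------------------------------------
  clr <- clr_correct(corrs$species1)
  grns <- list()
  for (th in config$grn_thresholds) {
    g <- build_grn(clr, tf_list = sim$truth$tf_ids, z_threshold = th)
    write_edge_list(g, file.path(out_dir, sprintf("grn_threshold_%g.tsv", th)))
    grns[[as.character(th)]] <- g
  }
  res$grns <- grns
  grn_main <- grns[[as.character(max(config$grn_thresholds))]]
  if (igraph::ecount(grn_main) == 0) grn_main <- grns[[1]]

  # -- cross-species comparison ----------------------------------------
  # synthetic ids map 1:1, relabel species2 into the shared namespace
  restricted <- restrict_to_homologs(nets$species1, nets$species2, sim$homolog_map)
  ov <- conserved_overlap_test(restricted$netA, restricted$netB,
                               n_perm = config$n_perm, seed = config$seed)
  dk <- diffk(restricted$netA, restricted$netB)
  dk <- diffk_pvalues(dk, null_fit = "central_quantile")
  readr::write_tsv(dk, file.path(out_dir, "diffk.tsv"))
  jsonlite::write_json(unclass(glance(ov)), file.path(out_dir, "overlap.json"),
                       auto_unbox = TRUE, digits = NA)
  res$overlap <- ov
  res$diffk <- dk

  # -- topology ---------------------------------------------------------
  topo <- list(
    density = network_density(nets$species1),
    small_world = small_world_odds(nets$species1,
                                   n_random = config$n_random_smallworld,
                                   seed = config$seed),
    degree_fit = tryCatch(degree_distribution_fit(nets$species1),
                          error = function(e) NULL)
  )
  prof <- centrality_profile(nets$species1)
  readr::write_tsv(prof, file.path(out_dir, "centrality_species1.tsv"))
  jsonlite::write_json(
    c(list(density = topo$density), unclass(glance(topo$small_world))),
    file.path(out_dir, "topology.json"), auto_unbox = TRUE, digits = NA)
  res$topology <- topo

  # -- specificity ------------------------------------------------------
  tau1 <- tau(sim$species1, types1)
  readr::write_tsv(tau1, file.path(out_dir, "tau_species1.tsv"))
  res$tau <- tau1

  # -- hierarchy --------------------------------------------------------
  hier <- assign_levels(grn_main, n_levels = config$hierarchy_levels,
                        seed = config$seed)
  readr::write_tsv(hier$levels, file.path(out_dir, "hierarchy_levels.tsv"))
  res$hierarchy <- hier

  # -- motifs -----------------------------------------------------------
  if (igraph::ecount(grn_main) >= 2) {
    mot <- motif_significance(grn_main, n_random = config$n_random_motifs,
                              seed = config$seed, sizes = config$motif_sizes)
    readr::write_tsv(mot, file.path(out_dir, "motifs.tsv"))
    res$motifs <- mot
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    tool = "hemanet",
    version = as.character(utils::packageVersion("hemanet")),
    seed = config$seed,
    config = serialize_config(config),
    stages = stages,
    files = lapply(setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(c(manifest, list(results = res)), class = "run_manifest")
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$simulate <- unclass(cfg$simulate)
  cfg
}

#' @export
print.run_manifest <- function(x, ...) {
  if (isTRUE(x$dry_run)) {
    cat("<run_manifest> dry run; stages:", paste(x$stages, collapse = " -> "), "\n")
  } else {
    cat(sprintf("<run_manifest> hemanet %s, seed %d, %d output files\n",
                x$version, x$seed, length(x$files)))
  }
  invisible(x)
}
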