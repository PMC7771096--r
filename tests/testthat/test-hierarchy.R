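out_tree_grn <- function() {
  # A -> B, A -> C, B -> D, C -> E; all five genes are TFs
  grn_network(data.frame(source = c("A", "A", "B", "C"),
                         target = c("B", "C", "D", "E")),
              tf_ids = c("A", "B", "C", "D", "E"))
}

test_that("annealing attains the exhaustive optimum on small GRNs", {
  g <- out_tree_grn()
  oracle <- bf_hierarchy_optimum(g, n_levels = 4)
  expect_equal(oracle, 4)  # the whole out-tree can point downward
  h <- assign_levels(g, n_levels = 4, n_iter = 3000, restarts = 3, seed = 1)
  expect_equal(h$objective_value, oracle)

  # random small GRNs against exhaustive enumeration, 3 levels (2..3)
  for (s in 1:4) {
    pg <- generate_planted_grn(n_tf = 6, n_target = 4, n_levels = 3,
                               downward_frac = 0.7, edges_per_node = 2,
                               seed = s)
    oracle <- bf_hierarchy_optimum(pg$grn, n_levels = 3)
    h <- assign_levels(pg$grn, n_levels = 3, n_iter = 3000, restarts = 3,
                       seed = s)
    expect_equal(h$objective_value, oracle)
  }
})

test_that("a 2-cycle yields objective 1 and a half-downward TF-TF fraction", {
  g <- grn_network(data.frame(source = c("A", "B"), target = c("B", "A")),
                   tf_ids = c("A", "B"))
  h <- assign_levels(g, n_levels = 4, n_iter = 1000, restarts = 2, seed = 3)
  expect_equal(h$objective_value, 1)
  expect_equal(h$downward_fraction, 0.5)
  expect_true(all(h$levels$level[h$levels$is_tf] %in% 2:4))
  expect_error(assign_levels(g, n_levels = 1), "n_levels")
})

test_that("downward_fraction counts targets at level 1", {
  g <- grn_network(data.frame(source = c("A", "A", "B", "B", "C"),
                              target = c("t1", "B", "t2", "C", "A")),
                   tf_ids = c("A", "B", "C"))
  lv <- data.frame(gene = c("A", "B", "C"), level = c(4, 3, 2))
  # A->t1 down, A->B down, B->t2 down, B->C down, C->A up: 4/5
  expect_equal(downward_fraction(g, lv), 0.8)
  lv2 <- data.frame(gene = c("A", "B", "C"), level = c(2, 3, 4))
  # A->t1 down, A->B up, B->t2 down, B->C up, C->A down: 3/5
  expect_equal(downward_fraction(g, lv2), 0.6)
  expect_error(downward_fraction(g, data.frame(gene = "A", level = 2)),
               "no level")

  pure_down <- grn_network(data.frame(source = c("A", "B"), target = c("t1", "t2")),
                           tf_ids = c("A", "B"))
  expect_equal(downward_fraction(pure_down,
                                 data.frame(gene = c("A", "B"), level = 4)), 1.0)
  single_up <- grn_network(data.frame(source = "B", target = "A"),
                           tf_ids = c("A", "B"))
  expect_equal(downward_fraction(single_up,
                                 data.frame(gene = c("A", "B"), level = c(3, 2))),
               0.0)
})

test_that("planted 90%-downward hierarchies are recovered above 85%", {
  fracs <- vapply(1:10, function(s) {
    pg <- generate_planted_grn(n_tf = 60, n_target = 600, n_levels = 4,
                               downward_frac = 0.9, edges_per_node = 2,
                               seed = s)
    h <- assign_levels(pg$grn, n_levels = 4, n_iter = 10000, restarts = 3,
                       seed = s)
    h$downward_fraction
  }, numeric(1))
  expect_gte(sum(fracs >= 0.85), 9)
})

test_that("rewiring destroys the pyramid shape of planted hierarchies", {
  pyramid <- function(grn, seed) {
    h <- assign_levels(grn, n_levels = 4, n_iter = 8000, restarts = 3,
                       seed = seed)
    lv <- h$levels[h$levels$is_tf, ]
    sum(lv$level == 4) < sum(lv$level == 2)
  }
  planted <- logical(10)
  rewired <- logical(10)
  for (s in 1:10) {
    # top-heavy planting: few TFs at the top, many at the bottom
    pg <- generate_planted_grn(n_tf = 40, n_target = 200, n_levels = 4,
                               downward_frac = 0.95, edges_per_node = 3,
                               seed = s)
    lvl <- setNames(pg$true_levels$level, pg$true_levels$gene)
    planted[s] <- pyramid(pg$grn, s)
    rw <- rewire_preserving_degrees(pg$grn, swaps_per_edge = 10, seed = s)
    rewired[s] <- pyramid(rw, s)
  }
  expect_gte(sum(planted), 8)
  expect_lte(sum(rewired), 5)
})

test_that("collaboration scores follow the co-targeting definition", {
  g <- grn_network(data.frame(
    source = c("A", "A", "A", "A", "B", "C"),
    target = c("t1", "t2", "t3", "t4", "t1", "t2")),
    tf_ids = c("A", "B", "C"))
  cs <- collaboration_scores(g)
  expect_equal(cs$collaboration_score[cs$tf == "A"], 0.5)  # t1, t2 co-targeted
  expect_equal(cs$collaboration_score[cs$tf == "B"], 1)
  expect_equal(cs$collaboration_score[cs$tf == "C"], 1)

  lone <- grn_network(data.frame(source = "A", target = c("t1")), tf_ids = "A")
  expect_equal(collaboration_scores(lone)$collaboration_score, 0)

  with_idle <- grn_network(data.frame(source = "A", target = "t1"),
                           tf_ids = c("A", "Z"), nodes = c("A", "Z", "t1"))
  expect_warning(collaboration_scores(with_idle), "no targets")
})

test_that("level summaries aggregate annotations, interactions and tau", {
  g <- grn_network(data.frame(source = c("A", "A", "B", "C", "C"),
                              target = c("B", "t1", "t1", "t2", "B")),
                   tf_ids = c("A", "B", "C"))
  h <- assign_levels(g, n_levels = 3, n_iter = 2000, restarts = 2, seed = 5)
  ann <- list(all_tfs = c("A", "B", "C"), none = character(),
              outside = c("A", "nonexistent_gene"))
  expect_warning(
    ls_tbl <- level_summaries(h, g, annotations = ann),
    "outside the GRN")
  expect_true(all(ls_tbl$frac_all_tfs == 1))
  expect_true(all(ls_tbl$frac_none == 0))
  expect_equal(sum(ls_tbl$n_genes), 3)

  inet <- gene_network(data.frame(gene1 = c("A", "A"), gene2 = c("B", "C")))
  tp <- tibble::tibble(gene = c("A", "B", "C"), tau = c(0.9, 0.5, 0.1))
  class(tp) <- c("tau_profile", class(tp))
  ls2 <- suppressWarnings(
    level_summaries(h, g, interaction_net = inet, tau_profile = tp))
  expect_true(all(c("mean_interaction_degree", "mean_tau") %in% names(ls2)))
})
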