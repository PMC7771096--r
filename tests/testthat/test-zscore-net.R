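test_that("X clusters give X(X-1)/2 comparison columns with signed shifts", {
  withr::with_seed(11, {
    m <- matrix(rpois(40 * 80, 2), 40, 80,
                dimnames = list(paste0("g", 1:40), paste0("c", 1:80)))
    m[1, 1:20] <- m[1, 1:20] + 20      # gene 1 high in cluster a
  })
  expr <- toy_expression(m)
  clust <- data.frame(cell_id = colnames(m),
                      cluster = rep(c("a", "b", "c", "d"), each = 20))
  dez <- cluster_de_zscores(expr, clust)
  expect_equal(ncol(dez), 6)
  expect_equal(colnames(dez), c("a|b", "a|c", "a|d", "b|c", "b|d", "c|d"))
  expect_gt(dez["g1", "a|b"], 0)
  expect_gt(dez["g1", "a|c"], 0)
  expect_lt(dez["g1", "b|c"], 2)  # no shift between b and c
})

test_that("null genes produce approximately standard-normal z-scores", {
  withr::with_seed(21, {
    m <- matrix(rpois(200 * 1000, 3), 200, 1000,
                dimnames = list(paste0("g", 1:200), paste0("c", 1:1000)))
  })
  expr <- toy_expression(m)
  clust <- data.frame(cell_id = colnames(m), cluster = rep(c("a", "b"), each = 500))
  expect_equal(ncol(cluster_de_zscores(expr, clust)), 1)
  clust3 <- data.frame(cell_id = colnames(m),
                       cluster = rep(c("a", "b", "c"), length.out = 1000))
  dez <- cluster_de_zscores(expr, clust3)
  expect_gte(mean(abs(dez[, "a|b"]) < 4), 0.99)
})

test_that("zero-variance genes and tiny clusters are handled", {
  m <- matrix(1, 5, 6, dimnames = list(paste0("g", 1:5), paste0("c", 1:6)))
  expr <- toy_expression(m)
  clust <- data.frame(cell_id = colnames(m), cluster = rep(c("a", "b", "c"), each = 2))
  dez <- cluster_de_zscores(expr, clust)
  expect_true(all(dez == 0))
  bad <- data.frame(cell_id = colnames(m), cluster = c("a", rep("b", 5)))
  expect_error(cluster_de_zscores(expr, bad), "cluster 'a'")
})

test_that("cell order does not change the DE z-matrix", {
  withr::with_seed(31, {
    m <- matrix(rpois(30 * 60, 2), 30, 60,
                dimnames = list(paste0("g", 1:30), paste0("c", 1:60)))
    clust <- data.frame(cell_id = colnames(m),
                        cluster = sample(rep(c("a", "b", "c"), each = 20)))
    perm <- sample(60)
  })
  expr1 <- toy_expression(m)
  expr2 <- toy_expression(m[, perm])
  dez1 <- cluster_de_zscores(expr1, clust)
  dez2 <- cluster_de_zscores(expr2, clust)
  expect_equal(dez1, dez2)
})

test_that("z-score correlations follow the textbook identities", {
  z <- rbind(
    gi = c(1, 2, 3),
    gj = c(1, 2, 4),
    gk = c(1, 2, 3),       # identical to gi
    gn = -c(1, 2, 3),      # negation of gi
    gc = c(5, 5, 5)        # constant
  )
  r <- zscore_correlation(z)
  expect_true(isSymmetric(r))
  expect_equal(unname(diag(r)), rep(1, 5))
  expect_true(all(r >= -1 & r <= 1))
  expect_equal(r["gi", "gk"], 1)
  expect_equal(r["gi", "gn"], -1)
  expect_equal(r["gi", "gj"], cor(c(1, 2, 3), c(1, 2, 4)), tolerance = 1e-12)
  expect_equal(r["gi", "gj"], 0.98198, tolerance = 1e-4)
  expect_equal(unname(r["gc", c("gi", "gj", "gn")]), rep(0, 3))
  expect_error(zscore_correlation(z[, 1:2]), "3 comparison")
})

test_that("top-k edge retention matches a full sort oracle", {
  r <- random_symmetric_corr(12, seed = 5)
  net <- build_coexpression_network(r, top_k = 5)
  tbl <- as_edge_tibble(net)
  # oracle: full sort of off-diagonal absolute values
  ut <- which(upper.tri(r), arr.ind = TRUE)
  vals <- abs(r[upper.tri(r)])
  top5 <- order(-vals)[1:5]
  oracle <- sort(edge_key_test(rownames(r)[ut[top5, 1]], rownames(r)[ut[top5, 2]]))
  got <- sort(edge_key_test(tbl$gene1, tbl$gene2))
  expect_equal(got, oracle)
  # signed ranking picks the largest raw values
  net_s <- build_coexpression_network(r, top_k = 5, rank_by = "signed")
  expect_true(all(as_edge_tibble(net_s)$weight >= sort(r[upper.tri(r)], decreasing = TRUE)[5]))
})

test_that("saturation, argmax and threshold equivalence hold", {
  r <- random_symmetric_corr(5, seed = 9)
  k5 <- build_coexpression_network(r, top_k = 10)
  expect_equal(igraph::ecount(k5), 10)
  expect_equal(igraph::vcount(k5), 5)

  r2 <- diag(5) * 0 + 0.1
  dimnames(r2) <- list(paste0("g", 1:5), paste0("g", 1:5))
  diag(r2) <- 1
  r2["g1", "g3"] <- r2["g3", "g1"] <- 0.95
  top1 <- as_edge_tibble(build_coexpression_network(r2, top_k = 1))
  expect_setequal(c(top1$gene1, top1$gene2), c("g1", "g3"))

  r3 <- random_symmetric_corr(8, seed = 2)
  t <- 0.4
  by_thresh <- build_coexpression_network(r3, threshold = t)
  k_equiv <- sum(abs(r3[upper.tri(r3)]) >= t)
  by_topk <- build_coexpression_network(r3, top_k = k_equiv)
  expect_setequal(edge_key_test(as_edge_tibble(by_thresh)$gene1, as_edge_tibble(by_thresh)$gene2),
                  edge_key_test(as_edge_tibble(by_topk)$gene1, as_edge_tibble(by_topk)$gene2))

  expect_error(build_coexpression_network(r3, top_k = 0), "top_k")
  expect_error(build_coexpression_network(r3, top_k = 10, threshold = 0.5),
               "exactly one")
})

test_that("planted modules are enriched among retained edges end to end", {
  # pooled Fisher table across 10 seeds
  tab <- matrix(0, 2, 2)
  for (s in 1:10) {
    sim <- generate_species_pair(
      species_pair_config(n_genes = 100, n_cells_per_species = 240, n_types = 6,
                          n_tfs = 10, module_count = 3, module_size = 7, seed = s))
    labs <- subset(sim$truth$type_of_cell, species == "species1")
    dez <- cluster_de_zscores(sim$species1,
                              data.frame(cell_id = labs$cell_id, cluster = labs$type))
    r <- zscore_correlation(dez)
    net <- build_coexpression_network(r, top_k = 200)
    mm <- sim$truth$module_membership
    in_mod <- !is.na(mm$module_species1)
    same <- outer(mm$module_species1, mm$module_species1, "==") &
      outer(in_mod, in_mod, "&")
    genes <- mm$gene
    el <- as_edge_tibble(net)
    retained <- matrix(FALSE, length(genes), length(genes), dimnames = list(genes, genes))
    retained[cbind(el$gene1, el$gene2)] <- TRUE
    retained <- retained | t(retained)
    ut <- upper.tri(retained)
    tab <- tab + table(factor(same[ut], c(TRUE, FALSE)),
                       factor(retained[ut], c(TRUE, FALSE)))
  }
  expect_lt(fisher.test(tab, alternative = "greater")$p.value, 0.01)
})
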