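toy_net <- function(edges, nodes = NULL) {
  gene_network(data.frame(gene1 = edges[, 1], gene2 = edges[, 2]), nodes = nodes)
}

test_that("homolog restriction relabels and drops unmapped genes", {
  netA <- toy_net(rbind(c("a1", "a2"), c("a2", "a3")))
  netB <- toy_net(rbind(c("b1", "b2"), c("b2", "b3")))
  full_map <- data.frame(species1 = c("a1", "a2", "a3"),
                         species2 = c("b1", "b2", "b3"))
  r <- restrict_to_homologs(netA, netB, full_map)
  expect_equal(igraph::ecount(r$netA), 2)
  expect_equal(igraph::ecount(r$netB), 2)
  expect_setequal(igraph::V(r$netB)$name, c("a1", "a2", "a3"))

  empty <- restrict_to_homologs(netA, netB,
                                data.frame(species1 = character(),
                                           species2 = character()))
  expect_equal(igraph::vcount(empty$netA), 0)
  expect_equal(igraph::vcount(empty$netB), 0)

  partial <- restrict_to_homologs(netA, netB,
                                  data.frame(species1 = "a1", species2 = "b1"))
  expect_equal(igraph::ecount(partial$netA), 0)

  dup <- data.frame(species1 = c("a1", "a1"), species2 = c("b1", "b2"))
  expect_error(restrict_to_homologs(netA, netB, dup), "one-to-one")
})

test_that("overlap test hits its boundary cases and ER expectation", {
  net <- generate_random_graph("erdos", 60, 100, seed = 2)
  same <- conserved_overlap_test(net, net, n_perm = 19, seed = 1)
  expect_equal(same$observed_overlap, 100)
  expect_equal(same$p_value, 1 / 20)

  withr::with_seed(5, {
    n <- 200
    e1 <- data.frame(gene1 = paste0("n", 1:50), gene2 = paste0("n", 51:100))
    e2 <- data.frame(gene1 = paste0("n", 101:150), gene2 = paste0("n", 151:200))
  })
  disjoint <- conserved_overlap_test(gene_network(e1, nodes = paste0("n", 1:200)),
                                     gene_network(e2, nodes = paste0("n", 1:200)),
                                     n_perm = 19, seed = 1)
  expect_equal(disjoint$observed_overlap, 0)
  expect_gt(disjoint$p_value, 0.5)

  # null mean matches |E1||E2|/C(n,2)
  netA <- generate_random_graph("erdos", 100, 400, seed = 3)
  netB <- generate_random_graph("erdos", 100, 500, seed = 4)
  ov <- conserved_overlap_test(netA, netB, n_perm = 200, seed = 9)
  expected <- 400 * 500 / choose(100, 2)
  expect_lte(abs(ov$null_mean - expected), 3 * ov$null_sd)
  expect_gte(ov$p_value, 1 / 201)
  expect_error(conserved_overlap_test(netA, netB, n_perm = 0), "n_perm")
})

test_that("diffk follows the printed formula and its symmetries", {
  # unnormalized hand case: k1 = 90, k2 = 0 in base 10
  netA <- toy_net(cbind("hub", paste0("x", 1:90)))
  netB <- toy_net(rbind(c("x1", "x2")), nodes = igraph::V(netA)$name)
  tab <- diffk(netA, netB, normalize = FALSE)
  expect_equal(tab$diffk[tab$gene == "hub"], log10(100) - log10(10))

  # antisymmetry under species swap
  nA <- generate_random_graph("erdos", 40, 60, seed = 1)
  nB <- generate_random_graph("erdos", 40, 80, seed = 2)
  d1 <- diffk(nA, nB)
  d2 <- diffk(nB, nA)
  expect_equal(d1$diffk, -d2$diffk[match(d1$gene, d2$gene)], tolerance = 1e-12)

  # equal normalized degree -> diffk 0
  d3 <- diffk(nA, nA)
  expect_true(all(abs(d3$diffk) < 1e-12))

  expect_error(diffk(toy_net(rbind(c("a", "b"))),
                     gene_network(data.frame(gene1 = character(),
                                             gene2 = character()),
                                  nodes = c("a", "b"))),
               "at least one edge")
})

test_that("diffk p-values are calibrated and BH matches a hand computation", {
  withr::with_seed(10, {
    tab <- tibble::tibble(gene = paste0("g", 1:10000),
                          k_species1 = 0, k_species2 = 0,
                          diffk = rnorm(10000))
  })
  out <- diffk_pvalues(tab, null_fit = "moments")
  ks <- suppressWarnings(stats::ks.test(out$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.02)

  out_r <- diffk_pvalues(tab, null_fit = "central_quantile")
  expect_lt(unname(suppressWarnings(stats::ks.test(out_r$p_value, "punif"))$statistic), 0.02)

  # value at the fitted center has p = 1
  tab2 <- tibble::tibble(gene = paste0("g", 1:21),
                         diffk = c(rep(c(-1, 1), 10), 0))
  out2 <- diffk_pvalues(tab2, null_fit = "moments")
  expect_equal(out2$p_value[out2$diffk == 0], 1)

  # BH on (0.01, 0.02, 0.03, 0.04) -> all 0.04
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  bh_idx <- order(out$p_value)[1:4]
  expect_true(all(out$fdr >= out$p_value))
})

test_that("tail selection matches a full sort oracle", {
  withr::with_seed(2, {
    tab <- tibble::tibble(gene = sprintf("g%02d", 1:20), diffk = rnorm(20))
  })
  tab$diffk[5] <- 0
  tails <- select_tails(tab, top_frac = 0.1, bottom_frac = 0.1,
                        conserved_frac = 0.2)
  expect_length(tails$top, 2)
  expect_length(tails$bottom, 2)
  expect_length(tails$conserved, 4)
  expect_setequal(tails$top, tab$gene[order(-tab$diffk)][1:2])
  expect_setequal(tails$bottom, tab$gene[order(tab$diffk)][1:2])
  expect_setequal(tails$conserved, tab$gene[order(abs(tab$diffk))][1:4])
  expect_true("g05" %in% tails$conserved)   # exact zero is always conserved

  tab100 <- tibble::tibble(gene = sprintf("g%03d", 1:100), diffk = rnorm(100))
  t100 <- select_tails(tab100)
  expect_equal(lengths(t100), c(top = 5, bottom = 5, conserved = 10))
  expect_error(select_tails(tab[1:5, ], top_frac = 0.05), "no genes")
})

test_that("odds-ratio curve matches direct counting on a toy matrix", {
  r <- random_symmetric_corr(6, seed = 12)
  ref <- data.frame(g1 = c("g1", "g2", "g3"), g2 = c("g2", "g3", "g4"))
  cuts <- c(0, 0.2, 0.5)
  curve <- enrichment_odds_ratio(r, ref, cuts)
  for (i in seq_along(cuts)) {
    ref_vals <- abs(c(r["g1", "g2"], r["g2", "g3"], r["g3", "g4"]))
    all_vals <- abs(r[upper.tri(r)])
    fr <- mean(ref_vals > cuts[i])
    fa <- mean(all_vals > cuts[i])
    expected <- if (fr == 0 || fa == 0) NA_real_ else fr / fa
    expect_equal(curve$odds_ratio[i], expected)
  }
  # reference = all pairs -> OR = 1 everywhere it is defined
  allp <- t(utils::combn(rownames(r), 2))
  c_all <- enrichment_odds_ratio(r, data.frame(allp), c(0, 0.3))
  expect_true(all(c_all$odds_ratio[!is.na(c_all$odds_ratio)] == 1))
})

test_that("Fisher gene-set enrichment matches the hypergeometric closed form", {
  universe <- paste0("g", 1:20)
  sets <- list(hit = paste0("g", 1:5), rand = paste0("g", 6:10))
  res <- gene_set_enrichment(paste0("g", 1:5), universe, sets)
  expect_equal(res$p_value[res$set == "hit"], 1 / choose(20, 5),
               tolerance = 1e-10)
  expect_equal(res$overlap[res$set == "rand"], 0)

  # independence-level overlap is not significant: table (1,4; 4,16)
  u25 <- paste0("g", 1:25)
  res2 <- gene_set_enrichment(paste0("g", c(1, 6:9)), u25,
                              list(s = paste0("g", c(1, 2:5))))
  expect_gt(res2$p_value, 0.5)
  expect_error(gene_set_enrichment("g1", character(), list(s = "g1")), "empty")
})
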