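# Network association: thresholded graphs, LCC statistics, resampling
# nulls, exact binomial enrichment.

complete_scores <- function(ids, score) {
  pairs <- t(utils::combn(ids, 2))
  tibble::tibble(gene1 = pairs[, 1], gene2 = pairs[, 2], score = score)
}

test_that("score threshold is strict and weights are discarded", {
  g <- build_network(complete_scores(paste0("g", 1:5), 900))
  expect_equal(igraph::gorder(g), 5)
  expect_equal(igraph::ecount(g), 10)
  expect_equal(igraph::ecount(build_network(complete_scores(paste0("g", 1:5), 600))), 0)
  expect_equal(igraph::ecount(build_network(complete_scores(paste0("g", 1:5), 700))), 0)
  expect_equal(igraph::ecount(build_network(complete_scores(paste0("g", 1:5), 700),
                                            strict = FALSE)), 10)
})

test_that("score tables round-trip through TSV with validation", {
  tab <- complete_scores(c("a", "b", "c"), c(100, 800, 701))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_score_table(path), tab)
  utils::write.table(dplyr::mutate(tab, score = score * 10), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_score_table(path), "0..1000")
})

test_that("LCC statistics follow the stated conventions", {
  edges <- tibble::tibble(
    gene1 = c("a", "b", "c", "a", "x", "y"),
    gene2 = c("b", "c", "d", "c", "y", "z"),
    score = 999)
  g <- build_network(edges)
  st <- lcc_stats(g, c("a", "b", "c", "d", "x", "y", "z"))
  expect_equal(st$n_lcc, 4)          # component {a,b,c,d} beats {x,y,z}
  expect_equal(st$n_link, 4)
  st2 <- lcc_stats(g, c("a", "b", "x", "y", "ghost"))
  expect_equal(st2, list(n_lcc = 2L, n_link = 1L))
  # edgeless induced subgraph
  expect_equal(lcc_stats(g, c("a", "d", "ghost")),
               list(n_lcc = 1L, n_link = 0L))
  expect_error(lcc_stats(g, character()), "empty")
  # complete 5-node subset -> (5, 10)
  k5 <- build_network(complete_scores(paste0("g", 1:5), 800))
  expect_equal(lcc_stats(k5, paste0("g", 1:5)), list(n_lcc = 5L, n_link = 10L))
})

test_that("LCC agrees with brute-force component enumeration", {
  set.seed(71)
  for (r in 1:15) {
    n <- sample(5:12, 1)
    ids <- paste0("n", 1:n)
    pairs <- t(utils::combn(ids, 2))
    keep <- runif(nrow(pairs)) < 0.25
    tab <- tibble::tibble(gene1 = pairs[, 1], gene2 = pairs[, 2],
                          score = ifelse(keep, 900, 100))
    g <- build_network(tab)
    subset <- sample(ids, sample(3:n, 1))
    got <- lcc_stats(g, subset)
    edges <- pairs[keep & pairs[, 1] %in% subset & pairs[, 2] %in% subset, ,
                   drop = FALSE]
    ref <- oracle_lcc(subset, edges)
    expect_equal(got$n_lcc, ref$n_lcc)
    if (got$n_lcc > 1) expect_equal(got$n_link, ref$n_link)
  }
})

test_that("resampling null is deterministic and flags degenerate draws", {
  set.seed(72)
  ids <- paste0("g", 1:12)
  tab <- complete_scores(ids, sample(0:1000, 66, replace = TRUE))
  g <- build_network(tab)
  igs_genes <- setNames(as.list(ids), paste0("tu", 1:12))
  obs <- lcc_stats(g, ids[1:5])
  set.seed(5); a <- resampling_null(g, igs_genes, 5, obs, n_resamples = 50)
  set.seed(5); b <- resampling_null(g, igs_genes, 5, obs, n_resamples = 50)
  expect_equal(a, b)
  # subset = all IGSs: every resample identical, sd 0, z flagged NA
  obs_all <- lcc_stats(g, ids)
  full <- resampling_null(g, igs_genes, 12, obs_all, n_resamples = 20)
  expect_true(full$degenerate_null)
  expect_true(is.na(full$z_lcc) && is.na(full$z_link))
})

test_that("z-scores are invariant under gene relabeling", {
  set.seed(73)
  ids <- paste0("g", 1:10)
  tab <- complete_scores(ids, sample(0:1000, 45, replace = TRUE))
  igs_genes <- setNames(as.list(ids), paste0("tu", 1:10))
  labels <- tibble::tibble(id = names(igs_genes),
                           cluster = rep(c("C0", "C1"), each = 5))
  set.seed(1)
  r1 <- network_association(build_network(tab), igs_genes, labels,
                            n_resamples = 60)
  # permute the gene namespace
  perm <- setNames(paste0("h", sample(10)), ids)
  tab2 <- dplyr::mutate(tab, gene1 = perm[gene1], gene2 = perm[gene2])
  igs_genes2 <- lapply(igs_genes, function(g) unname(perm[g]))
  set.seed(1)
  r2 <- network_association(build_network(tab2), igs_genes2, labels,
                            n_resamples = 60)
  expect_equal(r1$z_lcc, r2$z_lcc)
  expect_equal(r1$z_link, r2$z_link)
})

test_that("planted modules produce positive link z-scores", {
  set.seed(74)
  sim <- simulate_genome(fixture_spec(n_genes = 40, n_modules = 2))
  tab <- simulate_score_table(sim$truth, within_p = 0.9, between_p = 0.02)
  g <- build_network(tab)
  igs_genes <- setNames(sim$truth$gene_ids, sim$truth$tu_id)
  module1 <- sim$truth$tu_id[sim$truth$module == 1]
  obs <- lcc_stats(g, unlist(igs_genes[module1]))
  null <- resampling_null(g, igs_genes, length(module1), obs,
                          n_resamples = 200)
  expect_gt(null$z_link, 0)
  expect_lt(null$null_mean_link, obs$n_link)
})

test_that("exact binomial enrichment matches tail-sum arithmetic", {
  res <- binomial_enrichment(c(X = 5, Y = 5), c(X = 50, Y = 50))
  expect_equal(res$p_value[res$category == "X"], 1.0)        # k=5, n=10, p=.5
  res2 <- binomial_enrichment(c(X = 10, Y = 0), c(X = 50, Y = 50))
  expect_equal(res2$p_value[res2$category == "X"], 2 * 0.5^10)
  expect_equal(res2$direction, c("over", "under"))
  # two-sided p never exceeds 1 and BH is monotone in raw p
  set.seed(75)
  counts <- c(A = 3, B = 9, C = 1, D = 7)
  bg <- c(A = 100, B = 50, C = 200, D = 30)
  res3 <- binomial_enrichment(counts, bg)
  expect_true(all(res3$p_value <= 1 & res3$p_value > 0))
  expect_equal(res3$p_adjusted, stats::p.adjust(res3$p_value, "BH"))
  # empty cluster -> zero rows
  expect_equal(nrow(binomial_enrichment(integer(), bg)), 0)
})

test_that("two-sided doubling agrees with binom.test on symmetric cases", {
  for (k in c(0, 2, 5, 8, 10)) {
    ours <- binomial_enrichment(setNames(c(k, 10 - k), c("X", "Y")),
                                c(X = 500, Y = 500))
    ref <- stats::binom.test(k, 10, 0.5)$p.value
    expect_equal(ours$p_value[ours$category == "X"], ref, tolerance = 1e-12)
  }
})

test_that("enriched categories are flagged on planted tables", {
  set.seed(76)
  sim <- simulate_genome(fixture_spec(n_genes = 120))
  cats <- simulate_category_table(sim$truth, enrichment_factor = 12,
                                  target_class = "t_rich")
  igs_genes <- setNames(sim$truth$gene_ids, sim$truth$tu_id)
  labels <- tibble::tibble(id = sim$truth$tu_id,
                           cluster = ifelse(sim$truth$class == "t_rich",
                                            "C0", "C1"))
  res <- cluster_enrichment(cats, igs_genes, labels)
  hit <- res[res$cluster == "C0" & res$category == "A", ]
  expect_equal(hit$direction, "over")
  expect_lt(hit$p_adjusted, 0.01)
})
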