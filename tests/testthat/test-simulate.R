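test_that("simulated phylogeny is ultrametric with height 1 and bounded optima", {
  phy <- simulate_phylogeny_with_traits(2, sigma_bm = 4, seed = 5)
  depths <- ape::node.depth.edgelength(phy$tree)[1:2]
  expect_equal(unname(depths), c(1, 1))

  phy <- simulate_phylogeny_with_traits(40, sigma_bm = 8, seed = 6)
  expect_equal(max(ape::node.depth.edgelength(phy$tree)), 1)
  expect_equal(unname(range(phy$optima)), c(0, 35))
  expect_error(simulate_phylogeny_with_traits(1), "n_taxa")
})

test_that("zero Brownian rate collapses optima to midpoint with warning", {
  expect_warning(phy <- simulate_phylogeny_with_traits(10, sigma_bm = 0,
                                                       seed = 1),
                 "degenerate")
  expect_true(all(phy$optima == 17.5))
})

test_that("phylogeny and traits are deterministic given a seed", {
  a <- simulate_phylogeny_with_traits(15, 8, seed = 9)
  b <- simulate_phylogeny_with_traits(15, 8, seed = 9)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$optima, b$optima)
})

test_that("metacommunity abundances are normalized with a lognormal tail", {
  p <- simulate_metacommunity(50, 0, 0, seed = 1)
  expect_true(all(p == 1 / 50))
  p <- simulate_metacommunity(200, 0, 1.5, seed = 2)
  expect_lt(abs(sum(p) - 1), 1e-12)
  expect_true(all(p > 0))
  # heavy lognormal tail: most taxa rare (the paper's sparse-ASV setting)
  p <- simulate_metacommunity(1000, 0, 2, seed = 4)
  expect_gte(mean(p < 1e-4), 0.40)
})

test_that("sample columns always sum to the configured depth", {
  cfg <- simulation_config(
    n_taxa = 60, depth = 500, community_size_N = 500,
    groups = list(list(name = "a", n_samples = 3, env_mean = 5, env_sd = 1,
                       regime = "niche"),
                  list(name = "b", n_samples = 3, env_mean = 20, env_sd = 1,
                       regime = "neutral"),
                  list(name = "c", n_samples = 3, env_mean = 10, env_sd = 1,
                       regime = "drifted_pools")),
    seed = 3)
  ds <- simulate_dataset(cfg)
  expect_true(all(colSums(ds$counts) == 500))
  expect_identical(rownames(ds$counts), ds$tree$tip.label)
  expect_identical(colnames(ds$counts), ds$metadata$sample_id)
  expect_error(simulation_config(groups = list(
    list(name = "x", n_samples = 2, env_mean = 1, env_sd = 1,
         regime = "bogus"))), "regime")
})

test_that("identical config and seed reproduce the dataset exactly", {
  cfg <- simulation_config(n_taxa = 40, depth = 300, community_size_N = 300,
    groups = list(list(name = "a", n_samples = 4, env_mean = 5, env_sd = 1,
                       regime = "neutral")), seed = 11)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$counts, d2$counts)
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
  expect_identical(d1$metadata, d2$metadata)
})

test_that("infinite niche breadth recovers the metacommunity", {
  cfg <- simulation_config(n_taxa = 300, depth = 1e5, sigma_niche = 1e6,
    lognormal_sigma = 1,
    groups = list(list(name = "a", n_samples = 6, env_mean = 5, env_sd = 1,
                       regime = "niche")), seed = 13)
  ds <- simulate_dataset(cfg)
  mean_freq <- rowMeans(sweep(ds$counts, 2, colSums(ds$counts), "/"))
  tv <- 0.5 * sum(abs(mean_freq - ds$truth$pool))
  expect_lt(tv, 0.02)
})

test_that("divergent environments separate groups in Bray-Curtis space", {
  cfg <- simulation_config(n_taxa = 200, depth = 1000, sigma_niche = 2,
    lognormal_sigma = 1,
    groups = list(list(name = "lo", n_samples = 5, env_mean = 2, env_sd = 1,
                       regime = "niche"),
                  list(name = "hi", n_samples = 5, env_mean = 30, env_sd = 1,
                       regime = "niche")), seed = 17)
  ds <- simulate_dataset(cfg)
  bc <- bray_curtis(ds$counts)
  same <- outer(ds$metadata$group, ds$metadata$group, "==")
  expect_gt(mean(bc[!same & upper.tri(bc)]), mean(bc[same & upper.tri(bc)]))
})

test_that("synthetic dataset writes the standard file set", {
  cfg <- simulation_config(n_taxa = 30, depth = 200, community_size_N = 200,
    groups = list(list(name = "a", n_samples = 3, env_mean = 5, env_sd = 1,
                       regime = "niche"),
                  list(name = "b", n_samples = 3, env_mean = 20, env_sd = 1,
                       regime = "niche")), seed = 19)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_synthetic_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir,
    c("counts.tsv", "tree.nwk", "metadata.tsv", "truth.json")))))
  m <- read_count_table(file.path(dir, "counts.tsv"))
  expect_equal(unname(unclass(m))[rowSums(m) >= 0, ],
               unname(unclass(ds$counts)), ignore_attr = TRUE)
})
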