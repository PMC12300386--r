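test_that("rarefaction hits the exact depth and flags problems", {
  m <- random_counts(10, 4, 80)
  r <- rarefy(m, 30, seed = 1)
  expect_true(all(colSums(r) == 30))
  # identity when depth equals a sample's own total
  tot <- colSums(m)
  r2 <- rarefy(m, min(tot), seed = 2)
  same <- which(tot == min(tot))[1]
  expect_identical(r2[, same], m[, same])
  # forced draw
  m2 <- matrix(c(5L, 5L, 5L, 5L), 2,
               dimnames = list(c("A", "B"), c("x", "y")))
  expect_identical(unname(rarefy(m2, 10, seed = 3)[, 1]), c(5L, 5L))
  expect_error(rarefy(m, max(tot) + 1), colnames(m)[1])
})

test_that("rarefaction preserves expected relative abundances", {
  m <- matrix(c(3e5L, 7e5L), 2, 2,
              dimnames = list(c("A", "B"), c("s1", "s2")))
  props <- vapply(1:200, function(s) rarefy(m, 1e4, seed = s)[1, 1] / 1e4,
                  numeric(1))
  expect_lt(abs(mean(props) - 0.30), 0.01)
})

test_that("Shannon diversity matches closed forms in nats", {
  expect_equal(shannon(c(10, 10)), log(2))
  expect_equal(shannon(c(7, 0, 0)), 0)
  expect_equal(shannon(c(1, 1, 1, 1)), log(4))
  expect_error(shannon(c(0, 0)), "all-zero")
})

test_that("Faith's PD follows the rooted-subtree convention", {
  tr <- worked_tree()
  expect_equal(unname(faith_pd(c(A = 1, B = 1, C = 0), tr)), 3)
  expect_equal(unname(faith_pd(c(A = 0, B = 0, C = 5), tr)), 2)
  # the full tip set spans every branch: PD equals total branch length
  expect_equal(unname(faith_pd(c(A = 1, B = 1, C = 1), tr)),
               sum(tr$edge.length))
  expect_error(faith_pd(c(A = 1, Z = 1), tr), "Z")
})

test_that("Bray-Curtis matches the formula and bounds", {
  m <- matrix(c(2, 2, 1, 3), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(bray_curtis(m)["x", "y"], 0.25)
  ident <- cbind(x = c(3, 1), y = c(3, 1))
  rownames(ident) <- c("a", "b")
  expect_equal(bray_curtis(ident)["x", "y"], 0)
  disj <- cbind(x = c(1, 0), y = c(0, 1))
  rownames(disj) <- c("a", "b")
  expect_equal(bray_curtis(disj)["x", "y"], 1)
  zz <- cbind(x = c(0, 0), y = c(0, 0), z = c(1, 1))
  rownames(zz) <- c("a", "b")
  expect_error(bray_curtis(zz), "all-zero")
})

test_that("beta-MNTD matches hand-computed patristic averages", {
  tr <- worked_tree()
  m <- matrix(c(1L, 0L, 0L, 0L, 0L, 3L), 3,
              dimnames = list(c("A", "B", "C"), c("k", "l")))
  bm <- beta_mntd(m, tr)
  expect_equal(bm["k", "l"], 4)  # d(A, C) both directions
  ident <- matrix(c(2L, 1L, 1L, 2L, 1L, 1L), 3,
                  dimnames = list(c("A", "B", "C"), c("k", "l")))
  expect_equal(beta_mntd(ident, tr)["k", "l"], 0)
  even <- matrix(c(1L, 1L, 0L, 0L, 1L, 1L), 3,
                 dimnames = list(c("A", "B", "C"), c("k", "l")))
  expect_equal(beta_mntd(even, tr, weighted = TRUE),
               beta_mntd(even, tr, weighted = FALSE))
})

test_that("beta-MNTD agrees with picante's comdistnt", {
  set.seed(31)
  tr <- ape::rphylo(25, 1, 0)
  m <- random_counts(25, 6)
  rownames(m) <- tr$tip.label
  ours <- beta_mntd(m, tr)
  ref <- as.matrix(picante::comdistnt(t(m), stats::cophenetic(tr),
                                      abundance.weighted = TRUE))
  expect_equal(ours, ref[rownames(ours), colnames(ours)], tolerance = 1e-12)
})

test_that("PCoA reproduces classical-scaling geometry", {
  # equilateral triangle, side 1: two equal positive eigenvalues
  d <- matrix(1, 3, 3); diag(d) <- 0
  dimnames(d) <- list(letters[1:3], letters[1:3])
  p <- pcoa(d, k = 2)
  eig <- sort(p$eig, decreasing = TRUE)
  expect_equal(eig[1], eig[2], tolerance = 1e-9)
  expect_lt(abs(eig[3]), 1e-9)
  # collinear points: a single positive eigenvalue
  d2 <- as.matrix(dist(c(0, 1, 2)))
  dimnames(d2) <- list(letters[1:3], letters[1:3])
  p2 <- suppressWarnings(pcoa(d2, k = 2))
  expect_equal(sum(p2$eig > 1e-9), 1)
  # full-rank reconstruction of a random Euclidean configuration
  set.seed(5)
  x <- matrix(rnorm(6 * 3), 6)
  d3 <- as.matrix(dist(x))
  dimnames(d3) <- list(paste0("s", 1:6), paste0("s", 1:6))
  p3 <- pcoa(d3, k = 3)
  rec <- as.matrix(dist(p3$points))
  expect_lt(max(abs(rec - d3)), 1e-9)
  expect_error(pcoa(d3, k = 6), "n - 1")
})

test_that("SIMPER conserves mean between-group dissimilarity", {
  set.seed(41)
  for (i in 1:10) {
    m <- random_counts(15, 6)
    g <- rep(c("u", "v"), each = 3)
    sim <- simper_contributions(m, g, c("u", "v"))
    bc <- bray_curtis(m)
    between <- bc[g == "u", g == "v"]
    expect_lt(abs(attr(sim, "mean_between_bc") - mean(between)), 1e-9)
  }
})

test_that("SIMPER matches the single-pair formula and handles edge cases", {
  m <- matrix(c(1L, 0L, 0L, 1L), 2, dimnames = list(c("a", "b"),
                                                    c("s1", "s2")))
  sim <- simper_contributions(m, c("g1", "g2"), c("g1", "g2"))
  expect_equal(sim$contribution, c(0.5, 0.5))
  expect_equal(sim$percent, c(50, 50))
  m2 <- rbind(m, c(0L, 0L)); rownames(m2)[3] <- "absent"
  sim2 <- simper_contributions(m2, c("g1", "g2"), c("g1", "g2"))
  expect_equal(sim2$contribution[sim2$taxon == "absent"], 0)
  expect_error(simper_contributions(m, c("g1", "g2"), c("g1", "zz")), "zz")
  # aggregation sums counts before analysis
  agg <- simper_contributions(m2, c("g1", "g2"), c("g1", "g2"),
                              aggregate_by = c(a = "f1", b = "f1",
                                               absent = "f2"))
  expect_equal(nrow(agg), 2)
})

test_that("SIMPER cross-checks against vegan", {
  set.seed(43)
  m <- random_counts(12, 8)
  g <- rep(c("u", "v"), each = 4)
  ours <- simper_contributions(m, g, c("u", "v"))
  ref <- summary(vegan::simper(t(m), g))[["u_v"]]
  expect_equal(ours$contribution[match(rownames(ref), ours$taxon)],
               unname(ref$average), tolerance = 1e-9)
})

test_that("community overlap counts sets and shared fractions", {
  m <- matrix(0L, 3, 4, dimnames = list(c("A", "B", "C"),
                                        c("s1", "s2", "s3", "s4")))
  m[c("A", "B"), 1:2] <- 1L
  m[c("B", "C"), 3:4] <- 1L
  ov <- community_overlap(m, c("g1", "g1", "g2", "g2"))
  expect_equal(ov$pairwise["g1", "g2"], 1)
  expect_equal(ov$union_all, 3)
  expect_equal(ov$shared_fraction, 1 / 3)
  ident <- community_overlap(cbind(m[, 1:2], m[, 1:2]),
                             c("x", "x", "y", "y"))
  expect_equal(ident$shared_fraction, 1)
  disj <- matrix(c(1L, 0L, 0L, 1L), 2,
                 dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_equal(community_overlap(disj, c("x", "y"))$shared_fraction, 0)
})

test_that("taxon-environment screen recovers monotone relations", {
  md <- data.frame(sample_id = paste0("s", 1:6), group = "g",
                   env1 = 1:6, env2 = 6:1)
  rownames(md) <- md$sample_id
  m <- rbind(up = 1:6, down = 6:1, flat = rep(2, 6))
  colnames(m) <- md$sample_id
  res <- taxon_env_correlation(m, md, fit = TRUE)
  expect_equal(res$rho["up", "env1"], 1)
  expect_equal(res$rho["down", "env1"], -1)
  expect_equal(res$r_squared["up", "env1"], 1)
  expect_true(is.na(res$rho["flat", "env1"]))  # flagged, not an error
  expect_equal(res$p["up", "env1"], 0)
})

test_that("taxon-environment screen controls false positives under the null", {
  set.seed(53)
  false_rates <- replicate(100, {
    md <- data.frame(sample_id = paste0("s", 1:10), group = "g",
                     e1 = rnorm(10), e2 = rnorm(10))
    rownames(md) <- md$sample_id
    m <- matrix(rpois(5 * 10, 20), 5,
                dimnames = list(paste0("t", 1:5), md$sample_id))
    res <- taxon_env_correlation(m, md)
    mean(res$p_adj < 0.05, na.rm = TRUE)
  })
  expect_lte(mean(false_rates), 0.05)
})
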