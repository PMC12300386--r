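test_that("network construction keeps monotone pairs with positive sign", {
  set.seed(91)
  base <- rpois(10, 30)
  m <- rbind(t1 = base, t2 = base + 5L, t3 = rpois(10, 30))
  colnames(m) <- paste0("s", 1:10)
  storage.mode(m) <- "integer"
  net <- build_network(m, top_n = 3, rho_threshold = 0.6, alpha = 0.05)
  e <- net$edges
  expect_true(any(e$source == "t1" & e$target == "t2" |
                    e$source == "t2" & e$target == "t1"))
  expect_true(all(e$sign[abs(e$rho - 1) < 1e-9] == "+"))
  expect_equal(net$coverage, 1)  # top_n covers every taxon
  expect_error(build_network(m[, 1:3], top_n = 3), ">= 5")
})

test_that("constant taxa are excluded with a warning", {
  set.seed(93)
  m <- random_counts(6, 8)
  # equalize column totals so one row is constant in relative abundance
  m[1, ] <- 5L
  m[2, ] <- m[2, ] + max(colSums(m)) - colSums(m)
  expect_warning(build_network(m, top_n = 6, rho_threshold = 0.5),
                 "constant")
})

test_that("false-edge rate stays controlled for independent taxa", {
  set.seed(95)
  rates <- replicate(60, {
    m <- matrix(rpois(40 * 15, 20), 40,
                dimnames = list(paste0("t", 1:40), paste0("s", 1:15)))
    storage.mode(m) <- "integer"
    net <- suppressWarnings(build_network(m, top_n = 40,
                                          rho_threshold = 0.6))
    nrow(net$edges) / choose(40, 2)
  })
  expect_lte(mean(rates), 0.05)
})

test_that("topology metrics match closed forms on canonical graphs", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- paste0("n", 1:4)
  rep4 <- topology_report(k4, n_random = 10, seed = 1)
  expect_equal(rep4$density, 1)
  expect_equal(rep4$clustering_coefficient, 1)
  expect_equal(rep4$average_path_length, 1)
  expect_equal(rep4$diameter, 1)

  star <- igraph::make_star(4, mode = "undirected")
  igraph::V(star)$name <- paste0("n", 1:4)
  reps <- topology_report(star, n_random = 10, seed = 1)
  expect_equal(reps$clustering_coefficient, 0)
  expect_equal(reps$centralization_degree, 1)

  tri2 <- igraph::graph_from_edgelist(rbind(
    c(1, 2), c(2, 3), c(3, 1), c(4, 5), c(5, 6), c(6, 4)), directed = FALSE)
  igraph::V(tri2)$name <- paste0("n", 1:6)
  rep2 <- topology_report(tri2, n_random = 10, seed = 1)
  expect_equal(rep2$modularity, 0.5)
  expect_error(topology_report(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
})

test_that("Zi-Pi follows its definitions and threshold table", {
  # node 7 splits its 4 links 2/2 across two triangles: Pi = 0.5
  g <- igraph::graph_from_edgelist(rbind(
    c(1, 2), c(2, 3), c(3, 1),
    c(4, 5), c(5, 6), c(6, 4),
    c(7, 1), c(7, 2), c(7, 4), c(7, 5)), directed = FALSE)
  igraph::V(g)$name <- paste0("n", 1:7)
  mem <- c(1, 1, 1, 2, 2, 2, 1)
  roles <- suppressWarnings(zi_pi_roles(g, mem))
  expect_equal(roles$Pi[7], 0.5)
  expect_equal(roles$role[7], "peripheral")
  expect_equal(roles$Pi[3], 0)  # all links inside its module

  # planted hubs earn module-hub status; rule consistency for all nodes
  ph <- planted_hub_graph()
  top <- topology_report(ph, n_random = 10, seed = 3)
  r <- zi_pi_roles(ph, top$membership)
  hubs <- r$node %in% paste0("n", 0:3 * 13 + 1)
  expect_true(all(r$role[hubs] == "module_hub"))
  expect_true(all(r$Zi[hubs] >= 2.5 & r$Pi[hubs] < 0.62))
  expected <- ifelse(r$Zi >= 2.5,
                     ifelse(r$Pi >= 0.62, "network_hub", "module_hub"),
                     ifelse(r$Pi >= 0.62, "connector", "peripheral"))
  expect_identical(r$role, expected)
  expect_identical(r$keystone, r$role != "peripheral")
})

test_that("robustness endpoints and the star oracle hold exactly", {
  star <- igraph::make_star(8, center = 1, mode = "undirected")
  igraph::V(star)$name <- paste0("n", 1:8)
  mem <- rep(1, 8)
  roles <- suppressWarnings(zi_pi_roles(star, mem))
  roles$role[roles$node == "n1"] <- "module_hub"  # the sole hub-like node
  fr <- c(0, 1 / 8, 1)
  tgt <- robustness_curve(star, "targeted", fr, n_rep = 20, seed = 1,
                          roles = roles)
  expect_equal(tgt$mean[tgt$fraction == 0], 1)
  expect_equal(tgt$mean[tgt$fraction == 1 / 8], 0)  # center removal isolates all
  expect_equal(tgt$mean[tgt$fraction == 1], 0)
  rnd <- robustness_curve(star, "random", fr, n_rep = 2000, seed = 2)
  # exact enumeration: removing the center isolates every leaf (0);
  # removing a leaf leaves the other N - 1 nodes connected
  N <- 8
  exp_r <- (1 / N) * 0 + (1 - 1 / N) * (N - 1) / N
  expect_lt(abs(rnd$mean[rnd$fraction == 1 / 8] - exp_r), 0.03)
  expect_error(robustness_curve(star, "random", c(-0.1, 0.5)), "0, 1")
})

test_that("targeted degenerates to random without hubs, with a warning", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- paste0("n", 1:4)
  roles <- suppressWarnings(zi_pi_roles(k4, rep(1, 4)))
  expect_warning(robustness_curve(k4, "targeted", c(0, 0.5), n_rep = 5,
                                  seed = 1, roles = roles), "degenerates")
})

test_that("natural connectivity matches spectra and is monotone in edges", {
  k3 <- igraph::make_full_graph(3)
  expect_equal(natural_connectivity(k3),
               log((exp(2) + 2 * exp(-1)) / 3), tolerance = 1e-9)
  expect_equal(natural_connectivity(matrix(0, 5, 5)), 0)
  # adding any edge strictly increases it: all 4-node graphs
  pairs <- t(combn(4, 2))
  for (code in 0:62) {  # every proper subgraph of K4
    present <- as.logical(bitwAnd(code, 2^(0:5)))
    adj <- matrix(0, 4, 4)
    for (k in which(present)) adj[pairs[k, 1], pairs[k, 2]] <-
        adj[pairs[k, 2], pairs[k, 1]] <- 1
    base <- natural_connectivity(adj)
    for (k in which(!present)) {
      adj2 <- adj
      adj2[pairs[k, 1], pairs[k, 2]] <- adj2[pairs[k, 2], pairs[k, 1]] <- 1
      expect_gt(natural_connectivity(adj2), base)
    }
  }
})

test_that("natural-connectivity curves decline under removal", {
  g <- planted_hub_graph()
  cur <- natural_connectivity_curve(g, max_fraction = 0.5, n_rep = 10,
                                    seed = 5)
  expect_equal(nrow(cur), floor(0.5 * igraph::vcount(g)))
  expect_lt(cur$mean[nrow(cur)], cur$mean[1])
})

test_that("network construction is invariant to sample order", {
  set.seed(97)
  m <- random_counts(12, 10)
  n1 <- suppressWarnings(build_network(m, top_n = 12, rho_threshold = 0.5))
  n2 <- suppressWarnings(build_network(m[, sample(ncol(m))], top_n = 12,
                                       rho_threshold = 0.5))
  key <- function(n) {
    e <- n$edges
    sw <- e$source > e$target
    tmp <- e$source[sw]; e$source[sw] <- e$target[sw]; e$target[sw] <- tmp
    e <- e[order(e$source, e$target), c("source", "target", "rho")]
    rownames(e) <- NULL
    e
  }
  expect_equal(key(n1), key(n2), tolerance = 1e-12)
})
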