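# Shared fixtures, all built in code.

# The worked 3-tip tree used throughout the phylogenetic tests.
worked_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# Small deterministic count table (taxa x samples).
small_counts <- function() {
  m <- matrix(c(5L, 1L, 0L,
                0L, 2L, 7L), nrow = 3,
              dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  m
}

# Random valid count table.
random_counts <- function(n_taxa = 20, n_samples = 6, max_count = 50) {
  m <- matrix(rpois(n_taxa * n_samples, max_count / 4), n_taxa,
              dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                              sprintf("s%02d", seq_len(n_samples))))
  m[, colSums(m) == 0] <- 1L  # keep columns non-empty
  storage.mode(m) <- "integer"
  m
}

# Planted-hub modular graph: four star modules (one hub, 12 leaves)
# whose hubs form a ring.  Hubs are unambiguous module hubs.
planted_hub_graph <- function() {
  edges <- do.call(rbind, lapply(0:3, function(m)
    cbind(m * 13 + 1, m * 13 + 2:13)))
  hubs <- 0:3 * 13 + 1
  ring <- cbind(hubs, c(hubs[-1], hubs[1]))
  g <- igraph::graph_from_edgelist(rbind(edges, ring), directed = FALSE)
  igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
  g
}

# Distance matrix with two tight pairs: within-pair distance 0,
# between-pair distance 1 (the exhaustive PERMANOVA oracle).
two_pair_dist <- function() {
  d <- matrix(1, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  d[1, 2] <- d[2, 1] <- 0
  d[3, 4] <- d[4, 3] <- 0
  diag(d) <- 0
  d
}
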