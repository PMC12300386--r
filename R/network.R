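# Co-occurrence network construction (Spearman, thresholded on |rho| and
# adjusted p), topology and modular structure, Zi-Pi keystone
# classification, and stability experiments (robustness under node
# removal, natural connectivity).

#' Build a Spearman co-occurrence network
#'
#' Taxa are ranked by mean relative abundance and the `top_n` most
#' abundant kept (the usual guard against spurious rare-taxon edges);
#' Spearman rank correlations (average-rank ties, t-approximation p) are
#' computed across samples for all pairs, and edges retained when
#' `|rho| > rho_threshold` and the (BH-adjusted by default) p-value is
#' below `alpha`.  Isolated nodes are dropped and counted.
#'
#' @param counts taxa x samples matrix (>= 5 samples).
#' @param top_n taxa to keep by mean relative abundance (clamped to the
#'   number of available taxa with a message).
#' @param rho_threshold minimum absolute correlation (strict).
#' @param alpha significance level on the adjusted p-value.
#' @param adjust `"bh"` (Benjamini-Hochberg, default) or `"none"` (the
#'   raw-p variant).
#' @return object of class `cooccurrence_network`: `graph` (igraph),
#'   `nodes`, `edges` data.frames, `coverage` (summed mean relative
#'   abundance of selected taxa), `n_isolated_dropped`, `params`.
#' @export
build_network <- function(counts, top_n = 500, rho_threshold = 0.6,
                          alpha = 0.05, adjust = c("bh", "none")) {
  adjust <- match.arg(adjust)
  if (ncol(counts) < 5) stop_fmt("network construction needs >= 5 samples")
  rel <- sweep(counts, 2, colSums(counts), "/")
  mra <- rowMeans(rel)
  if (top_n > nrow(counts)) {
    message(sprintf("top_n = %d exceeds the %d available taxa; using all",
                    top_n, nrow(counts)))
    top_n <- nrow(counts)
  }
  keep <- names(sort(mra, decreasing = TRUE))[seq_len(top_n)]
  coverage <- sum(mra[keep])
  sub <- rel[keep, , drop = FALSE]
  const <- apply(sub, 1, stats::sd) == 0
  if (any(const)) {
    warn_fmt("%d constant taxa excluded from correlation", sum(const))
    sub <- sub[!const, , drop = FALSE]
  }
  nt <- nrow(sub)
  n <- ncol(sub)
  rho <- stats::cor(t(sub), method = "spearman")
  iu <- which(upper.tri(rho), arr.ind = TRUE)
  rv <- rho[upper.tri(rho)]
  tt <- rv * sqrt((n - 2) / pmax(1 - rv^2, 1e-300))
  pv <- 2 * stats::pt(-abs(tt), n - 2)
  pv[abs(rv) >= 1] <- 0
  p_adj <- if (adjust == "bh") stats::p.adjust(pv, method = "BH") else pv
  sel <- abs(rv) > rho_threshold & p_adj < alpha
  edges <- data.frame(source = rownames(sub)[iu[sel, 1]],
                      target = rownames(sub)[iu[sel, 2]],
                      rho = rv[sel],
                      sign = ifelse(rv[sel] > 0, "+", "-"),
                      p_raw = pv[sel], p_adj = p_adj[sel],
                      stringsAsFactors = FALSE)
  used <- union(edges$source, edges$target)
  n_isolated <- nt - length(used)
  nodes <- data.frame(taxon = used,
                      mean_rel_abundance = mra[used],
                      stringsAsFactors = FALSE, row.names = NULL)
  tax <- attr(counts, "taxonomy")
  if (!is.null(tax)) nodes$taxonomy <- tax[used]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  out <- list(graph = g, nodes = nodes, edges = edges,
              coverage = coverage, n_isolated_dropped = n_isolated,
              params = list(top_n = top_n, rho_threshold = rho_threshold,
                            alpha = alpha, adjust = adjust))
  class(out) <- "cooccurrence_network"
  out
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("co-occurrence network: %d nodes, %d edges (%d+/%d-), coverage %.3f\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$sign == "+"),
              sum(x$edges$sign == "-"), x$coverage))
  invisible(x)
}

.as_igraph <- function(net) {
  if (inherits(net, "cooccurrence_network")) net$graph
  else if (inherits(net, "igraph")) net
  else stop_fmt("expected a cooccurrence_network or igraph object")
}

#' Topology report for a co-occurrence network
#'
#' Node/edge counts, positive/negative edges, average degree, density
#' `2E / (N(N-1))`, mean local clustering (nodes of degree < 2
#' contribute 0), average path length and diameter on the largest
#' connected component (with its node share reported), Freeman degree /
#' betweenness / closeness centralizations, Louvain modules and
#' modularity M, and relative modularity
#' `RM = (M_obs - mean M_ER) / mean M_ER` against `n_random`
#' Erdos-Renyi graphs with identical node and edge counts.
#'
#' @param net `cooccurrence_network` or igraph graph.
#' @param n_random Erdos-Renyi replicates for RM.
#' @param seed RNG seed (Louvain and the ER null are seeded).
#' @return list of class `topology_report` (also carries `membership`).
#' @export
topology_report <- function(net, n_random = 100, seed = NULL) {
  g <- .as_igraph(net)
  N <- igraph::vcount(g)
  E <- igraph::ecount(g)
  if (N == 0 || E == 0) stop_fmt("empty network")
  sign_attr <- igraph::edge_attr(g, "sign")
  n_pos <- if (!is.null(sign_attr)) sum(sign_attr == "+") else NA_integer_
  n_neg <- if (!is.null(sign_attr)) sum(sign_attr == "-") else NA_integer_

  comps <- igraph::components(g)
  lcc_ids <- which(comps$membership == which.max(comps$csize))
  lcc <- igraph::induced_subgraph(g, lcc_ids)

  local_cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  local_cc[is.na(local_cc)] <- 0  # degree < 2 contributes 0

  with_rng(seed, {
    comm <- igraph::cluster_louvain(g)
    m_obs <- igraph::modularity(comm)
    m_er <- vapply(seq_len(n_random), function(i) {
      er <- igraph::sample_gnm(N, E)
      igraph::modularity(igraph::cluster_louvain(er))
    }, numeric(1))
  })
  rm_idx <- (m_obs - mean(m_er)) / mean(m_er)

  out <- list(
    n_nodes = N, n_edges = E, n_positive = n_pos, n_negative = n_neg,
    average_degree = 2 * E / N,
    density = igraph::edge_density(g),
    clustering_coefficient = mean(local_cc),
    average_path_length = igraph::mean_distance(lcc),
    diameter = igraph::diameter(lcc),
    lcc_share = max(comps$csize) / N,
    centralization_degree = {
      dg <- igraph::degree(g)
      if (N > 2) sum(max(dg) - dg) / ((N - 1) * (N - 2)) else NA_real_
    },
    centralization_betweenness = igraph::centr_betw(g)$centralization,
    centralization_closeness = igraph::centr_clo(lcc)$centralization,
    modularity = m_obs,
    relative_modularity = rm_idx,
    n_modules = length(unique(igraph::membership(comm))),
    membership = igraph::membership(comm))
  class(out) <- "topology_report"
  out
}

#' @export
print.topology_report <- function(x, ...) {
  cat("network topology\n")
  for (f in c("n_nodes", "n_edges", "n_positive", "n_negative",
              "average_degree", "density", "clustering_coefficient",
              "average_path_length", "diameter", "lcc_share",
              "centralization_degree", "centralization_betweenness",
              "centralization_closeness", "modularity",
              "relative_modularity", "n_modules"))
    cat(sprintf("  %-27s %s\n", f, fmt_real(x[[f]])))
  invisible(x)
}

#' @export
as.data.frame.topology_report <- function(x, ...) {
  f <- setdiff(names(x), "membership")
  data.frame(metric = f, value = vapply(x[f], as.numeric, numeric(1)),
             row.names = NULL)
}

#' Zi-Pi node roles
#'
#' Within-module degree z-score
#' `Zi = (k_within - mean k_within(module)) / sd k_within(module)` and
#' among-module connectivity `Pi = 1 - sum_s (k_is / k_i)^2`.  Roles:
#' peripheral (Zi < 2.5, Pi < 0.62), connector (Zi < 2.5, Pi >= 0.62),
#' module hub (Zi >= 2.5, Pi < 0.62), network hub (Zi >= 2.5,
#' Pi >= 0.62).  Modules whose within-degree spread is zero get Zi = 0
#' for their members (flagged).  Keystones = connectors, module hubs and
#' network hubs.
#'
#' @param net `cooccurrence_network` or igraph graph.
#' @param membership module id per node (e.g. from [topology_report()]).
#' @return data.frame of class `node_roles`: node, module, degree,
#'   within_degree, Zi, Pi, role, keystone.
#' @export
zi_pi_roles <- function(net, membership) {
  g <- .as_igraph(net)
  N <- igraph::vcount(g)
  mem <- as.integer(membership)
  if (length(mem) != N) stop_fmt("membership must cover all %d nodes", N)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  deg <- rowSums(adj)
  kw <- vapply(seq_len(N), function(i) sum(adj[i, mem == mem[i]]),
               numeric(1))
  zi <- numeric(N)
  flagged <- FALSE
  for (m in unique(mem)) {
    idx <- which(mem == m)
    s <- stats::sd(kw[idx])
    if (is.na(s) || s < 1e-12) {
      zi[idx] <- 0
      flagged <- TRUE
    } else {
      zi[idx] <- (kw[idx] - mean(kw[idx])) / s
    }
  }
  if (flagged)
    warn_fmt("module(s) with zero within-degree spread; Zi set to 0 there")
  pi_ <- vapply(seq_len(N), function(i) {
    ks <- tapply(adj[i, ], mem, sum)
    1 - sum((ks / deg[i])^2)
  }, numeric(1))
  role <- ifelse(zi >= 2.5,
                 ifelse(pi_ >= 0.62, "network_hub", "module_hub"),
                 ifelse(pi_ >= 0.62, "connector", "peripheral"))
  df <- data.frame(node = igraph::V(g)$name %||% as.character(seq_len(N)),
                   module = mem, degree = deg, within_degree = kw,
                   Zi = zi, Pi = pi_, role = role,
                   keystone = role != "peripheral",
                   stringsAsFactors = FALSE)
  class(df) <- c("node_roles", "data.frame")
  df
}

# Remove a node set, cascade-delete newly isolated nodes, return the
# surviving fraction.  (Removing an isolated node never changes another
# node's degree, so one cascade pass suffices.)
.robustness_after <- function(adj, remove_idx, cascade = TRUE) {
  N <- nrow(adj)
  keep <- setdiff(seq_len(N), remove_idx)
  if (!length(keep)) return(0)
  if (!cascade) return(length(keep) / N)
  sub <- adj[keep, keep, drop = FALSE]
  sum(rowSums(sub) > 0) / N
}

#' Robustness under node removal
#'
#' For each removal fraction f, deletes `ceiling(f N)` nodes - uniformly
#' at random (`strategy = "random"`) or module hubs first in decreasing
#' Zi, then randomly among the rest (`strategy = "targeted"`) - then
#' cascade-deletes nodes whose degree dropped to zero.  Robustness is
#' the proportion of nodes remaining.
#'
#' @param net `cooccurrence_network` or igraph graph.
#' @param strategy `"random"` or `"targeted"`.
#' @param fractions removal-fraction grid in \[0, 1\].
#' @param n_rep replicates per fraction.
#' @param seed RNG seed.
#' @param roles `node_roles` (required for targeted removal; with no
#'   module hubs, targeted degenerates to random with a warning).
#' @param cascade also drop newly isolated nodes (default; the
#'   no-cascade variant keeps them).
#' @return data.frame of class `stability_curves`: fraction, mean, sd,
#'   strategy.
#' @export
robustness_curve <- function(net, strategy = c("random", "targeted"),
                             fractions = seq(0, 1, by = 0.05),
                             n_rep = 100, seed = NULL, roles = NULL,
                             cascade = TRUE) {
  strategy <- match.arg(strategy)
  if (any(fractions < 0 | fractions > 1))
    stop_fmt("fractions must lie in [0, 1]")
  g <- .as_igraph(net)
  N <- igraph::vcount(g)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  hub_order <- integer(0)
  if (strategy == "targeted") {
    if (is.null(roles)) stop_fmt("targeted removal requires node roles")
    hubs <- which(roles$role %in% c("module_hub", "network_hub"))
    if (!length(hubs)) {
      warn_fmt("no module hubs; targeted removal degenerates to random")
    } else {
      hub_order <- hubs[order(-roles$Zi[hubs])]
    }
  }
  res <- with_rng(seed, {
    do.call(rbind, lapply(fractions, function(f) {
      n_rm <- ceiling(f * N)
      vals <- vapply(seq_len(n_rep), function(r) {
        if (n_rm == 0) return(1)
        if (strategy == "targeted" && length(hub_order)) {
          first <- hub_order[seq_len(min(n_rm, length(hub_order)))]
          rest <- setdiff(seq_len(N), first)
          extra <- if (n_rm > length(first))
            sample(rest, n_rm - length(first)) else integer(0)
          idx <- c(first, extra)
        } else {
          idx <- sample(N, n_rm)
        }
        .robustness_after(adj, idx, cascade)
      }, numeric(1))
      data.frame(fraction = f, mean = mean(vals), sd = stats::sd(vals),
                 strategy = strategy)
    }))
  })
  class(res) <- c("stability_curves", "data.frame")
  res
}

#' Natural connectivity of a graph
#'
#' `ln((1/N) sum_i exp(lambda_i))` over the eigenvalues of the binary
#' symmetric adjacency matrix; a spectral measure of route redundancy.
#' An edgeless graph scores 0.
#'
#' @param net `cooccurrence_network`, igraph graph, or adjacency matrix.
#' @return numeric scalar.
#' @export
natural_connectivity <- function(net) {
  adj <- if (is.matrix(net)) (net != 0) * 1
  else igraph::as_adjacency_matrix(.as_igraph(net), sparse = FALSE)
  adj <- (adj != 0) * 1
  N <- nrow(adj)
  if (N == 0) stop_fmt("empty graph")
  lam <- eigen(adj, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(lam)
  mx + log(sum(exp(lam - mx))) - log(N)
}

#' Natural-connectivity decline under random node removal
#'
#' Removes nodes one at a time in random order up to `max_fraction` of
#' the network, recomputing natural connectivity on all remaining nodes
#' after each removal, and averages the curve over `n_rep` removal
#' orders.
#'
#' @param net `cooccurrence_network` or igraph graph (>= 2 nodes).
#' @param max_fraction largest fraction of nodes removed.
#' @param n_rep number of random removal orders.
#' @param seed RNG seed.
#' @return data.frame of class `stability_curves`: n_removed, fraction,
#'   mean, sd.
#' @export
natural_connectivity_curve <- function(net, max_fraction = 0.8,
                                       n_rep = 20, seed = NULL) {
  g <- .as_igraph(net)
  N <- igraph::vcount(g)
  if (N < 2) stop_fmt("need >= 2 nodes")
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  adj <- (adj != 0) * 1
  n_steps <- floor(max_fraction * N)
  curves <- with_rng(seed, {
    vapply(seq_len(n_rep), function(r) {
      ord <- sample(N)
      vapply(seq_len(n_steps), function(s) {
        keep <- setdiff(seq_len(N), ord[seq_len(s)])
        if (length(keep) == 0) return(NA_real_)
        sub <- adj[keep, keep, drop = FALSE]
        lam <- eigen(sub, symmetric = TRUE, only.values = TRUE)$values
        mx <- max(lam)
        mx + log(sum(exp(lam - mx))) - log(length(keep))
      }, numeric(1))
    }, numeric(n_steps))
  })
  curves <- matrix(curves, nrow = n_steps)
  res <- data.frame(n_removed = seq_len(n_steps),
                    fraction = seq_len(n_steps) / N,
                    mean = rowMeans(curves, na.rm = TRUE),
                    sd = apply(curves, 1, stats::sd, na.rm = TRUE))
  class(res) <- c("stability_curves", "data.frame")
  res
}
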