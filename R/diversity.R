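# Alpha/beta diversity, ordination, permutation tests, SIMPER, overlap
# counting and taxon-environment association screens.
#
# Count tables follow the package convention taxa x samples.  vegan and
# picante expect samples x species, so internal calls transpose.

#' Rarefy a count table to a common depth
#'
#' A single seeded subsampling draw without replacement per sample
#' (matching the common one-table workflow, not an average over draws).
#' Taxa that end up all-zero are retained and flagged.
#'
#' @param counts taxa x samples integer matrix.
#' @param depth target reads per sample; must not exceed any sample sum.
#' @param seed RNG seed.
#' @return rarefied matrix with attribute `zero_taxa` (ids of taxa that
#'   lost all reads).
#' @export
rarefy <- function(counts, depth, seed = NULL) {
  validate_count_table(counts)
  cs <- colSums(counts)
  shallow <- colnames(counts)[cs < depth]
  if (length(shallow))
    stop_fmt("depth %d exceeds sample total(s) for: %s", depth,
             paste(shallow, collapse = ", "))
  out <- with_rng(seed, t(withCallingHandlers(
    vegan::rrarefy(t(counts), depth),
    # vegan advises about large counts; our validation already enforces
    # integer observed counts
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })))
  storage.mode(out) <- "integer"
  attr(out, "zero_taxa") <- rownames(out)[rowSums(out) == 0]
  attr(out, "taxonomy") <- attr(counts, "taxonomy")
  out
}

#' Shannon-Wiener diversity (natural log)
#'
#' `H = -sum(q_i log q_i)` over taxa present, with `q` the relative
#' abundances of one sample.  Natural log (nats); divide by `log(2)` for
#' bits.
#'
#' @param x abundance vector, or taxa x samples matrix (one value per
#'   sample).
#' @return numeric (named by sample for matrix input).
#' @export
shannon <- function(x) {
  if (is.matrix(x)) {
    if (any(colSums(x) <= 0)) stop_fmt("all-zero sample column")
    return(vegan::diversity(t(x), index = "shannon"))
  }
  if (sum(x) <= 0) stop_fmt("all-zero abundance vector")
  unname(vegan::diversity(x, index = "shannon"))
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal rooted subtree spanning a
#' sample's taxa, including the path to the root (the `picante::pd`
#' default; single-taxon samples therefore score their root-to-tip
#' distance, not zero).
#'
#' @param x abundance vector named by taxon, or taxa x samples matrix.
#' @param tree rooted [ape::phylo] whose tips cover all present taxa.
#' @return numeric PD per sample.
#' @export
faith_pd <- function(x, tree) {
  validate_tree(tree)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1, dimnames = list(names(x), "s1"))
  present <- rownames(x)[rowSums(x) > 0]
  miss <- setdiff(present, tree$tip.label)
  if (length(miss)) stop_fmt("taxa missing from tree: %s",
                             paste(miss, collapse = ", "))
  comm <- t(x)
  res <- picante::pd(comm, tree, include.root = TRUE)
  stats::setNames(res$PD, rownames(res))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d_kl = sum|x_ik - x_il| / sum(x_ik + x_il)` on the supplied scale
#' (counts or relative abundances).
#'
#' @param counts taxa x samples matrix (>= 2 samples).
#' @return square symmetric matrix in \[0, 1\].
#' @export
bray_curtis <- function(counts) {
  if (ncol(counts) < 2) stop_fmt("need >= 2 samples")
  zero <- colnames(counts)[colSums(counts) == 0]
  if (length(zero) >= 2)
    stop_fmt("Bray-Curtis undefined between all-zero samples: %s",
             paste(zero, collapse = ", "))
  as.matrix(vegan::vegdist(t(counts), method = "bray"))
}

# Patristic (tip-to-tip) distances aligned to the taxa of a count table.
.patristic <- function(counts, tree) {
  miss <- setdiff(rownames(counts), tree$tip.label)
  if (length(miss)) stop_fmt("taxa missing from tree: %s",
                             paste(utils::head(miss, 5), collapse = ", "))
  D <- stats::cophenetic(tree)
  D[rownames(counts), rownames(counts)]
}

# Core beta-MNTD on a patristic matrix D and a taxa x samples weight
# matrix F (columns sum to 1 over present taxa).  perm relabels taxa
# across D (identity = observed; random = the betaNTI regional-pool
# null, where abundances stay untouched).
.bmntd_core <- function(D, F_, perm = seq_len(nrow(F_))) {
  M <- .bmntd_pairs(D, F_, as.integer(perm))
  dimnames(M) <- list(colnames(F_), colnames(F_))
  M
}

# Abundance weights for beta-MNTD: relative abundance among present taxa
# (weighted) or 1/richness (unweighted).
.bmntd_weights <- function(counts, weighted) {
  if (any(colSums(counts) <= 0)) stop_fmt("sample with no present taxa")
  if (weighted) sweep(counts, 2, colSums(counts), "/")
  else sweep(counts > 0, 2, colSums(counts > 0), "/")
}

#' Between-sample mean nearest taxon distance (beta-MNTD)
#'
#' For samples k, l:
#' `0.5 * (sum_i f_ik min_j d_ij + sum_j f_jl min_i d_ij)` over present
#' taxa, with `d` the patristic distance and `f` relative abundances
#' among present taxa (`weighted = TRUE`, default) or `1/richness`.
#'
#' @param counts taxa x samples matrix.
#' @param tree rooted phylogeny covering the taxa.
#' @param weighted abundance-weighted (default) or incidence-based.
#' @return square symmetric matrix.
#' @export
beta_mntd <- function(counts, tree, weighted = TRUE) {
  validate_tree(tree)
  D <- .patristic(counts, tree)
  .bmntd_core(D, .bmntd_weights(counts, weighted))
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centering plus eigendecomposition via [stats::cmdscale()].
#' Negative eigenvalues are reported, never silently dropped; proportion
#' explained is relative to the sum of positive eigenvalues.
#'
#' @param d square dissimilarity matrix (or `dist`).
#' @param k number of axes (\eqn{\le n - 1}).
#' @return list of class `pcoa_result`: `points` (n x k), `eig`,
#'   `prop_explained`.
#' @export
pcoa <- function(d, k = 2) {
  d <- as_square_dist(d)
  n <- nrow(d)
  if (k > n - 1) stop_fmt("k must be <= n - 1 = %d", n - 1)
  fit <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < k)
    warn_fmt("only %d axes with positive eigenvalues available", ncol(pts))
  pos <- sum(fit$eig[fit$eig > 0])
  out <- list(points = pts, eig = fit$eig,
              prop_explained = if (pos > 0) fit$eig / pos else rep(NA, n))
  class(out) <- "pcoa_result"
  out
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d axes returned\n",
              nrow(x$points), ncol(x$points)))
  k <- min(4, length(x$eig))
  cat("eigenvalues:", paste(fmt_real(x$eig[seq_len(k)]), collapse = " "),
      if (length(x$eig) > k) "..." else "", "\n")
  invisible(x)
}

# All distinct permutations of a label vector (multiset permutations),
# returned as a list.  Used for exhaustive PERMANOVA.
.multiset_perms <- function(labels) {
  rec <- function(pool) {
    if (length(pool) == 1) return(list(pool))
    out <- list()
    for (u in unique(pool)) {
      rest <- pool[-match(u, pool)]
      for (tail in rec(rest)) out[[length(out) + 1]] <- c(u, tail)
    }
    out
  }
  rec(labels)
}

# One-factor pseudo-F from a squared-distance decomposition.
.permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(upper_vals(d2)) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1)
      ss_within <- ss_within +
        sum(upper_vals(d2[idx, idx, drop = FALSE])) / length(idx)
  }
  g <- length(unique(groups))
  ss_between <- ss_total - ss_within
  f <- (ss_between / (g - 1)) / (ss_within / (n - g))
  c(F = f, R2 = ss_between / ss_total)
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Pseudo-F from the squared-distance decomposition
#' `SS_total = (1/n) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`.  The p-value uses
#' the estimator `(1 + #extreme) / (1 + n_perm)`; when the number of
#' distinct labelings is at most `n_perm` the permutation distribution is
#' enumerated exhaustively instead (p = fraction of all labelings with
#' `F >= F_obs`, the observed labeling included).
#'
#' @param d distance matrix or `dist`.
#' @param groups group labels aligned with the rows of `d`.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list of class `permanova_result`: `pseudo_F`, `R2`, `p`,
#'   `n_perm`, `exhaustive`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- as_square_dist(d)
  groups <- as.character(groups)
  n <- nrow(d)
  if (length(groups) != n) stop_fmt("groups must match the matrix rows")
  g <- length(unique(groups))
  if (g < 2) stop_fmt("need >= 2 groups")
  if (n == g) stop_fmt("no residual degrees of freedom (one sample per group)")
  d2 <- d^2
  obs <- .permanova_f(d2, groups)

  n_distinct <- factorial(n) / prod(factorial(table(groups)))
  if (is.finite(n_distinct) && n_distinct <= n_perm) {
    perms <- .multiset_perms(groups)
    fs <- vapply(perms, function(gg) .permanova_f(d2, gg)[["F"]], numeric(1))
    p <- mean(fs >= obs[["F"]])
    exhaustive <- TRUE
    n_used <- length(perms)
  } else {
    fs <- with_rng(seed, vapply(seq_len(n_perm), function(i)
      .permanova_f(d2, sample(groups))[["F"]], numeric(1)))
    p <- (1 + sum(fs >= obs[["F"]])) / (1 + n_perm)
    exhaustive <- FALSE
    n_used <- n_perm
  }
  out <- list(pseudo_F = unname(obs[["F"]]), R2 = unname(obs[["R2"]]),
              p = p, n_perm = n_used, exhaustive = exhaustive)
  class(out) <- "permanova_result"
  out
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, R2 = %.4g, p = %.4g (%s, %d perms)\n",
              x$pseudo_F, x$R2, x$p,
              if (x$exhaustive) "exhaustive" else "sampled", x$n_perm))
  invisible(x)
}

# Rank-based (partial) Mantel statistic on upper triangles.
.mantel_r <- function(a, b, cc = NULL) {
  ra <- rank(a); rb <- rank(b)
  if (is.null(cc)) return(stats::cor(ra, rb))
  rc <- rank(cc)
  ea <- stats::resid(stats::lm(ra ~ rc))
  eb <- stats::resid(stats::lm(rb ~ rc))
  if (stats::sd(ea) < 1e-12 || stats::sd(eb) < 1e-12) {
    warn_fmt("control matrix leaves no residual variation; partial r set to 0")
    return(0)
  }
  stats::cor(ea, eb)
}

#' (Partial) Mantel test with Spearman correlation
#'
#' Rank correlation of the upper triangles of two distance matrices; the
#' partial version correlates the residuals of both after rank-regressing
#' on the control matrix.  Significance by jointly permuting rows and
#' columns of `dist_a`, one-sided on `r >= r_obs`, with the estimator
#' `(1 + #extreme) / (1 + n_perm)`.
#'
#' @param dist_a,dist_b square distance matrices with matching ids.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @param control optional third matrix to partial out.
#' @return list of class `mantel_result`: `r`, `p`, `n_perm`, `partial`.
#' @export
mantel_test <- function(dist_a, dist_b, n_perm = 999, seed = NULL,
                        control = NULL) {
  a <- as_square_dist(dist_a); b <- as_square_dist(dist_b)
  n <- nrow(a)
  if (n < 4) stop_fmt("need >= 4 samples")
  if (nrow(b) != n) stop_fmt("matrix dimensions differ")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b)))
    stop_fmt("matrix ids differ")
  cc <- if (!is.null(control)) as_square_dist(control) else NULL
  va <- upper_vals(a); vb <- upper_vals(b)
  if (stats::sd(va) < 1e-12 || stats::sd(vb) < 1e-12)
    stop_fmt("constant distance triangle; Mantel r undefined")
  vc <- if (!is.null(cc)) upper_vals(cc) else NULL
  r_obs <- .mantel_r(va, vb, vc)
  perm_r <- with_rng(seed, vapply(seq_len(n_perm), function(i) {
    ord <- sample(n)
    suppressWarnings(.mantel_r(upper_vals(a[ord, ord]), vb, vc))
  }, numeric(1)))
  p <- (1 + sum(perm_r >= r_obs)) / (1 + n_perm)
  out <- list(r = r_obs, p = p, n_perm = n_perm,
              partial = !is.null(control))
  class(out) <- "mantel_result"
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%sMantel: r = %.4g, p = %.4g (%d perms)\n",
              if (x$partial) "partial " else "", x$r, x$p, x$n_perm))
  invisible(x)
}

#' Distance-decay of community similarity
#'
#' Haversine geographic distances (Earth radius 6371.0088 km), Bray-
#' Curtis dissimilarity, Mantel test of distance vs dissimilarity, and a
#' least-squares line of similarity (`1 - BC`) against distance for
#' plotting.
#'
#' @param counts taxa x samples matrix.
#' @param metadata data.frame with `latitude` and `longitude` for every
#'   sample (rows aligned by sample id).
#' @param n_perm Mantel permutations.
#' @param seed RNG seed.
#' @param control optional distance matrix to partial out (e.g.
#'   environmental distance).
#' @return list of class `distance_decay`: `mantel`, `slope` (per km),
#'   `intercept`, `r_squared`, `geo_km`, `dissimilarity`.
#' @export
distance_decay <- function(counts, metadata, n_perm = 999, seed = NULL,
                           control = NULL) {
  ids <- colnames(counts)
  md <- metadata[ids, , drop = FALSE]
  bad <- ids[is.na(md$latitude) | is.na(md$longitude)]
  if (length(bad) || is.null(md$latitude) || is.null(md$longitude))
    stop_fmt("missing coordinates for sample(s): %s",
             paste(if (length(bad)) bad else ids, collapse = ", "))
  xy <- cbind(md$longitude, md$latitude)
  geo <- geosphere::distm(xy,
                          fun = function(p1, p2)
                            geosphere::distHaversine(p1, p2, r = 6371008.8))
  geo <- geo / 1000  # km
  dimnames(geo) <- list(ids, ids)
  bc <- bray_curtis(counts)
  mt <- mantel_test(geo, bc, n_perm = n_perm, seed = seed, control = control)
  sim <- 1 - upper_vals(bc)
  km <- upper_vals(geo)
  fit <- stats::lm(sim ~ km)
  out <- list(mantel = mt, slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              r_squared = summary(fit)$r.squared,
              geo_km = geo, dissimilarity = bc)
  class(out) <- "distance_decay"
  out
}

#' @export
print.distance_decay <- function(x, ...) {
  cat(sprintf("distance-decay: slope = %.4g per km, R2 = %.4g; Mantel r = %.4g, p = %.4g\n",
              x$slope, x$r_squared, x$mantel$r, x$mantel$p))
  invisible(x)
}

#' SIMPER: per-taxon contributions to between-group dissimilarity
#'
#' Taxon t's contribution is the mean over all between-group sample
#' pairs (k, l) of `|x_tk - x_tl| / sum_u(x_uk + x_ul)`; contributions
#' sum to the mean between-group Bray-Curtis dissimilarity.  Counts can
#' be aggregated first (e.g. to family level) via `aggregate_by`.
#'
#' @param counts taxa x samples matrix.
#' @param groups group labels aligned with the columns.
#' @param pair length-2 character vector naming the two groups.
#' @param aggregate_by optional named character vector taxon ->
#'   aggregate label; counts are summed within labels before analysis.
#' @return data.frame of class `simper_table` (taxon, contribution,
#'   percent, cumulative_percent), sorted by contribution, with
#'   attribute `mean_between_bc`.
#' @export
simper_contributions <- function(counts, groups, pair,
                                 aggregate_by = NULL) {
  groups <- as.character(groups)
  if (!all(pair %in% groups)) stop_fmt("unknown group in pair: %s",
                                       paste(setdiff(pair, groups),
                                             collapse = ", "))
  if (!is.null(aggregate_by)) {
    lab <- aggregate_by[rownames(counts)]
    if (anyNA(lab)) stop_fmt("aggregate_by misses taxa: %s",
                             paste(utils::head(rownames(counts)[is.na(lab)], 5),
                                   collapse = ", "))
    counts <- rowsum(counts, lab)
  }
  a <- which(groups == pair[1]); b <- which(groups == pair[2])
  contrib <- numeric(nrow(counts))
  n_pairs <- 0L
  for (k in a) for (l in b) {
    denom <- sum(counts[, k] + counts[, l])
    contrib <- contrib + abs(counts[, k] - counts[, l]) / denom
    n_pairs <- n_pairs + 1L
  }
  contrib <- contrib / n_pairs
  tot <- sum(contrib)
  ord <- order(-contrib, rownames(counts))
  df <- data.frame(taxon = rownames(counts)[ord],
                   contribution = contrib[ord],
                   percent = 100 * contrib[ord] / tot,
                   stringsAsFactors = FALSE)
  df$cumulative_percent <- cumsum(df$percent)
  attr(df, "mean_between_bc") <- tot
  class(df) <- c("simper_table", "data.frame")
  df
}

#' Presence overlap between groups
#'
#' A taxon is "present" in a group when it has a positive count in at
#' least one of the group's samples.  Returns per-group richness, all
#' subset intersection cardinalities, and the shared fraction
#' `|intersection of all| / |union of all|`.
#'
#' @param counts taxa x samples matrix.
#' @param groups group labels aligned with the columns.
#' @return list of class `overlap_counts`.
#' @export
community_overlap <- function(counts, groups) {
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) < 2) stop_fmt("need >= 2 groups")
  sets <- lapply(gl, function(g)
    rownames(counts)[rowSums(counts[, groups == g, drop = FALSE] > 0) > 0])
  names(sets) <- gl
  pairwise <- outer(seq_along(gl), seq_along(gl),
                    Vectorize(function(i, j)
                      length(intersect(sets[[i]], sets[[j]]))))
  dimnames(pairwise) <- list(gl, gl)
  subsets <- list()
  for (k in 2:length(gl)) {
    for (combo in utils::combn(gl, k, simplify = FALSE)) {
      subsets[[paste(combo, collapse = "&")]] <-
        length(Reduce(intersect, sets[combo]))
    }
  }
  un <- length(Reduce(union, sets))
  inter <- length(Reduce(intersect, sets))
  out <- list(richness = vapply(sets, length, integer(1)),
              pairwise = pairwise, subset_intersections = subsets,
              intersection_all = inter, union_all = un,
              shared_fraction = if (un > 0) inter / un else NA_real_,
              sets = sets)
  class(out) <- "overlap_counts"
  out
}

#' @export
print.overlap_counts <- function(x, ...) {
  cat(sprintf("overlap: union %d, shared %d (fraction %.3g)\n",
              x$union_all, x$intersection_all, x$shared_fraction))
  print(x$richness)
  invisible(x)
}

# Spearman rho with average-rank ties and t-approximation p-value.
.spearman_t <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 4) return(c(rho = NA_real_, p = NA_real_, n = n))
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(c(rho = rho, p = 0, n = n))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * stats::pt(-abs(tt), n - 2), n = n)
}

#' Taxon-environment Spearman association screen
#'
#' Spearman rho (average-rank ties, t-approximation p) between taxon
#' abundances and environmental variables, with Benjamini-Hochberg
#' adjustment across the whole screen.  Constant vectors give flagged
#' `NA` cells, not failure.  Optionally adds per-pair least-squares
#' linear fits (slope, intercept, R-squared).
#'
#' @param counts taxa x samples matrix.
#' @param metadata data.frame with numeric environment columns, rows =
#'   samples.
#' @param taxa,env optional subsets (default: all taxa / all numeric
#'   metadata columns except coordinates).
#' @param fit also compute linear fits.
#' @return list of class `taxon_env_cor` with matrices `rho`, `p`,
#'   `p_adj` (taxa x env) and, if `fit`, `slope`, `intercept`,
#'   `r_squared`.
#' @export
taxon_env_correlation <- function(counts, metadata, taxa = NULL,
                                  env = NULL, fit = FALSE) {
  md <- metadata[colnames(counts), , drop = FALSE]
  if (is.null(env)) {
    num <- names(md)[vapply(md, is.numeric, logical(1))]
    env <- setdiff(num, c("latitude", "longitude"))
  }
  if (is.null(taxa)) taxa <- rownames(counts)
  if (!length(env)) stop_fmt("no environmental columns selected")
  rho <- p <- matrix(NA_real_, length(taxa), length(env),
                     dimnames = list(taxa, env))
  if (fit) slope <- intercept <- r2 <- rho
  for (i in seq_along(taxa)) for (j in seq_along(env)) {
    x <- counts[taxa[i], ]
    y <- md[[env[j]]]
    if (sum(is.finite(x) & is.finite(y)) < 4)
      stop_fmt("fewer than 4 complete observations for %s ~ %s",
               taxa[i], env[j])
    st <- .spearman_t(x, y)
    rho[i, j] <- st[["rho"]]; p[i, j] <- st[["p"]]
    if (fit && is.finite(st[["rho"]])) {
      lf <- stats::lm(x ~ y)
      slope[i, j] <- stats::coef(lf)[2]
      intercept[i, j] <- stats::coef(lf)[1]
      r2[i, j] <- suppressWarnings(summary(lf)$r.squared)
    }
  }
  p_adj <- p
  ok <- !is.na(p)
  p_adj[ok] <- stats::p.adjust(p[ok], method = "BH")
  out <- list(rho = rho, p = p, p_adj = p_adj)
  if (fit) out <- c(out, list(slope = slope, intercept = intercept,
                              r_squared = r2))
  class(out) <- "taxon_env_cor"
  out
}
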