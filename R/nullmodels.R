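# Null-model partitioning of community assembly processes: the beta
# nearest taxon index (betaNTI) quantifies phylogenetic turnover against
# a taxon-shuffle null, the Bray-Curtis Raup-Crick index (RCbray)
# quantifies compositional turnover against a richness- and
# abundance-preserving null, and the two are combined pair-by-pair into
# the five-process framework: heterogeneous selection (betaNTI > 2),
# homogeneous selection (betaNTI < -2), dispersal limitation
# (|betaNTI| <= 2, RC > 0.95), homogenizing dispersal (RC < -0.95) and
# undominated (|RC| <= 0.95).

#' Beta nearest taxon index (betaNTI)
#'
#' For every sample pair, `betaNTI = (bMNTD_obs - mean bMNTD_null) / sd
#' bMNTD_null`, where the null shuffles taxon labels across the
#' patristic distance matrix (a regional-pool randomization over the
#' whole table) while abundances stay untouched.  Pairs whose null has
#' zero spread (e.g. a star phylogeny) are returned as `NA` with a
#' warning and are excluded from partition denominators downstream.
#'
#' @param counts taxa x samples matrix.
#' @param tree rooted phylogeny covering the taxa.
#' @param n_null number of label shuffles (>= 99; 999 is standard).
#' @param seed RNG seed.
#' @param weighted abundance-weighted beta-MNTD (default), or
#'   incidence-based.
#' @return square symmetric matrix of betaNTI values (diagonal `NA`).
#' @export
compute_bnti <- function(counts, tree, n_null = 999, seed = NULL,
                         weighted = TRUE) {
  if (n_null < 99) stop_fmt("n_null must be >= 99")
  validate_tree(tree)
  D <- .patristic(counts, tree)
  F_ <- .bmntd_weights(counts, weighted)
  obs <- .bmntd_core(D, F_)
  S <- ncol(counts)
  nt <- nrow(counts)
  iu <- upper.tri(obs)
  sum1 <- sum2 <- numeric(sum(iu))
  with_rng(seed, for (b in seq_len(n_null)) {
    v <- .bmntd_core(D, F_, perm = sample(nt))[iu]
    sum1 <- sum1 + v
    sum2 <- sum2 + v^2
  })
  mu <- sum1 / n_null
  sdv <- sqrt(pmax(sum2 / n_null - mu^2, 0) * n_null / (n_null - 1))
  bnti_v <- (obs[iu] - mu) / sdv
  und <- sdv < 1e-12
  if (any(und)) {
    warn_fmt("%d pair(s) have zero null spread; betaNTI undefined", sum(und))
    bnti_v[und] <- NA_real_
  }
  out <- matrix(NA_real_, S, S, dimnames = dimnames(obs))
  out[iu] <- bnti_v
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

# Bray-Curtis between two non-negative vectors.
.bc_pair <- function(x, y) sum(abs(x - y)) / sum(x + y)

# Draw one Raup-Crick null community: keep the observed richness, choose
# the present taxa with probability proportional to occupancy, give each
# one individual, then allocate the remaining reads proportionally to
# regional relative abundance.
.rc_null_sample <- function(richness, total, occupancy, p) {
  idx <- sample.int(length(p), richness, prob = occupancy)
  x <- numeric(length(p))
  x[idx] <- 1
  extra <- total - richness
  if (extra > 0)
    x[idx] <- x[idx] + stats::rmultinom(1, extra, p[idx])[, 1]
  x
}

#' Bray-Curtis Raup-Crick index (RCbray)
#'
#' For each sample pair, builds `n_null` null pairs in which each sample
#' keeps its observed richness and total reads: present taxa are chosen
#' with probability proportional to occupancy across all samples, then
#' individuals are allocated proportionally to regional relative
#' abundance.  `RC = 2 ((#{null BC < obs} + 0.5 #{null BC = obs}) /
#' n_null) - 1`, in \[-1, 1\]; ties take half weight.
#'
#' @param counts taxa x samples matrix.
#' @param n_null null replicates (>= 99).
#' @param seed RNG seed.
#' @param occupancy,pool optional taxon weights for the null (presence
#'   probability and regional relative abundance); by default estimated
#'   from `counts`.  Supplying them lets a larger reference table define
#'   the regional pool.
#' @return square symmetric matrix of RCbray values (diagonal `NA`).
#' @export
compute_rcbray <- function(counts, n_null = 999, seed = NULL,
                           occupancy = NULL, pool = NULL) {
  if (n_null < 99) stop_fmt("n_null must be >= 99")
  validate_count_table(counts)
  S <- ncol(counts)
  occupancy <- occupancy %||% rowSums(counts > 0)
  p <- pool %||% (rowSums(counts) / sum(counts))
  richness <- colSums(counts > 0)
  totals <- colSums(counts)
  if (any(richness > sum(occupancy > 0)))
    stop_fmt("sample richness exceeds the taxon pool")
  out <- matrix(NA_real_, S, S,
                dimnames = list(colnames(counts), colnames(counts)))
  with_rng(seed, for (k in seq_len(S - 1)) for (l in (k + 1):S) {
    obs <- .bc_pair(counts[, k], counts[, l])
    less <- ties <- 0L
    for (b in seq_len(n_null)) {
      nk <- .rc_null_sample(richness[k], totals[k], occupancy, p)
      nl <- .rc_null_sample(richness[l], totals[l], occupancy, p)
      bc <- .bc_pair(nk, nl)
      if (bc < obs - 1e-12) less <- less + 1L
      else if (abs(bc - obs) <= 1e-12) ties <- ties + 1L
    }
    out[k, l] <- out[l, k] <- 2 * ((less + 0.5 * ties) / n_null) - 1
  })
  out
}

#' Partition assembly processes from betaNTI and RCbray
#'
#' Per pair: `betaNTI > 2` heterogeneous selection; `betaNTI < -2`
#' homogeneous selection; otherwise `RC > 0.95` dispersal limitation,
#' `RC < -0.95` homogenizing dispersal, `|RC| <= 0.95` undominated.
#' Fractions are computed over within-group pairs by default; `pairs`
#' selects between-group or all pairs instead (different assembly
#' signals live on different pair sets: selection within environmentally
#' coherent groups, dispersal limitation between separated pools).
#' Pairs with undefined betaNTI are excluded from denominators and
#' counted in `n_excluded`.  Because the share of, say, homogeneous
#' selection is sometimes reported relative to deterministic pairs only,
#' a `deterministic_split` table gives that alternative normalization.
#'
#' @param bnti square betaNTI matrix.
#' @param rcbray square RCbray matrix with identical ids.
#' @param groups group labels aligned with the matrix rows.
#' @param pairs which sample pairs enter the fractions: `"within"`
#'   (default, per group plus a pooled `all_within` row), `"between"` or
#'   `"all"` (one pooled row).
#' @return object of class `assembly_partition` with `fractions` (long
#'   data.frame: group, process, n_pairs, fraction), `deterministic_split`,
#'   `pair_labels` (per-pair process assignments) and `n_excluded`.
#' @export
partition_processes <- function(bnti, rcbray, groups,
                                pairs = c("within", "between", "all")) {
  pairs <- match.arg(pairs)
  if (!all(dim(bnti) == dim(rcbray)))
    stop_fmt("betaNTI and RCbray matrices must be aligned")
  groups <- as.character(groups)
  S <- nrow(bnti)
  if (length(groups) != S) stop_fmt("groups must match matrix rows")
  procs <- c("heterogeneous_selection", "homogeneous_selection",
             "dispersal_limitation", "homogenizing_dispersal", "undominated")

  classify <- function(b, r) {
    if (is.na(b)) return(NA_character_)
    if (b > 2) return("heterogeneous_selection")
    if (b < -2) return("homogeneous_selection")
    if (is.na(r)) return(NA_character_)
    if (r > 0.95) return("dispersal_limitation")
    if (r < -0.95) return("homogenizing_dispersal")
    "undominated"
  }

  pl <- list()
  for (k in seq_len(S - 1)) for (l in (k + 1):S) {
    scope <- if (groups[k] == groups[l]) "within" else "between"
    if (pairs == "within" && scope != "within") next
    if (pairs == "between" && scope != "between") next
    pl[[length(pl) + 1]] <- data.frame(
      i = rownames(bnti)[k], j = rownames(bnti)[l],
      group = if (scope == "within") groups[k] else "between",
      bnti = bnti[k, l], rcbray = rcbray[k, l],
      process = classify(bnti[k, l], rcbray[k, l]),
      stringsAsFactors = FALSE)
  }
  if (!length(pl)) stop_fmt("no pairs in the requested scope")
  pair_labels <- do.call(rbind, pl)
  n_excluded <- sum(is.na(pair_labels$process))
  valid <- pair_labels[!is.na(pair_labels$process), , drop = FALSE]
  if (!nrow(valid)) stop_fmt("no valid pairs (all betaNTI undefined)")

  frac_for <- function(sub, label) {
    tab <- table(factor(sub$process, levels = procs))
    data.frame(group = label, process = procs,
               n_pairs = as.integer(tab),
               fraction = as.numeric(tab) / nrow(sub),
               stringsAsFactors = FALSE)
  }
  if (pairs == "within") {
    parts <- lapply(split(valid, valid$group),
                    function(s) frac_for(s, s$group[1]))
    parts$all_within <- frac_for(valid, "all_within")
    fractions <- do.call(rbind, c(parts, make.row.names = FALSE))
  } else {
    fractions <- frac_for(valid, pairs)
  }

  det <- valid[valid$process %in% procs[1:2], , drop = FALSE]
  deterministic_split <- if (nrow(det)) {
    tab <- table(factor(det$process, levels = procs[1:2]))
    data.frame(process = procs[1:2], n_pairs = as.integer(tab),
               fraction_of_deterministic = as.numeric(tab) / nrow(det),
               stringsAsFactors = FALSE)
  } else {
    data.frame(process = character(0), n_pairs = integer(0),
               fraction_of_deterministic = numeric(0))
  }

  out <- list(fractions = fractions,
              deterministic_split = deterministic_split,
              pair_labels = pair_labels, n_excluded = n_excluded,
              scope = pairs)
  class(out) <- "assembly_partition"
  out
}

#' Dominant assembly process of a partition
#' @param x an `assembly_partition`.
#' @param group which fractions row-group to use (default: the pooled
#'   scope row).
#' @return the process name with the largest fraction.
#' @export
dominant_process <- function(x, group = NULL) {
  stopifnot(inherits(x, "assembly_partition"))
  lab <- group %||% if (x$scope == "within") "all_within" else x$scope
  f <- x$fractions[x$fractions$group == lab, ]
  f$process[which.max(f$fraction)]
}

#' @export
print.assembly_partition <- function(x, ...) {
  cat(sprintf("assembly partition (%s pairs, %d excluded)\n",
              x$scope, x$n_excluded))
  print(x$fractions, row.names = FALSE)
  invisible(x)
}
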