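# Synthetic-data generator: seeded phylogenies with Brownian salinity
# niches, lognormal metacommunities, and multi-group count tables under
# controlled assembly regimes.  Every downstream stage of the package is
# exercised against these ground-truth datasets.
#
# All randomness flows from one master seed through named streams
# (tree, traits, pools, env, space, sampling), so each component is
# individually reproducible.

#' Build and validate a simulation configuration
#'
#' Defaults emulate a three-habitat, salinity-gradient design: two
#' groundwater zones under niche (salinity) selection at different mean
#' salinities, and a surface reservoir assembled neutrally from the
#' regional pool.
#'
#' @param n_taxa number of taxa in the regional pool (>= 10).
#' @param groups list of group descriptors, each a list with `name`,
#'   `n_samples`, `env_mean`, `env_sd`, `regime` (one of `"niche"`,
#'   `"neutral"`, `"drifted_pools"`).
#' @param sigma_bm Brownian trait rate (salinity units per sqrt branch
#'   length).
#' @param sigma_niche niche breadth (salinity units); small values mean
#'   strong filtering.
#' @param migration_m immigration probability per replacement in (0, 1].
#' @param community_size_N local community size for neutral dynamics.
#' @param depth reads per sample after sequencing (column sums).
#' @param lognormal_mu,lognormal_sigma metacommunity log-abundance
#'   parameters; larger sigma means more rare taxa.
#' @param dirichlet_conc concentration for per-group pool perturbation in
#'   the `drifted_pools` regime; smaller means stronger pool drift.
#' @param transect_km spatial extent of the 1-D sampling transect.
#' @param seed master seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa = 1000,
                              groups = list(
                                list(name = "groundwater_in", n_samples = 9,
                                     env_mean = 3, env_sd = 1,
                                     regime = "niche"),
                                list(name = "groundwater_out", n_samples = 9,
                                     env_mean = 30, env_sd = 2,
                                     regime = "niche"),
                                list(name = "reservoir", n_samples = 9,
                                     env_mean = 6, env_sd = 1.5,
                                     regime = "neutral")),
                              sigma_bm = 8, sigma_niche = 1.5,
                              migration_m = 0.3, community_size_N = 5000,
                              depth = 3000, lognormal_mu = 0,
                              lognormal_sigma = 1.5, dirichlet_conc = 50,
                              transect_km = 20, seed = 1) {
  cfg <- list(n_taxa = n_taxa, groups = groups, sigma_bm = sigma_bm,
              sigma_niche = sigma_niche, migration_m = migration_m,
              community_size_N = community_size_N, depth = depth,
              lognormal_mu = lognormal_mu, lognormal_sigma = lognormal_sigma,
              dirichlet_conc = dirichlet_conc, transect_km = transect_km,
              seed = seed)
  if (cfg$n_taxa < 10) stop_fmt("n_taxa must be >= 10")
  if (cfg$depth < 100) stop_fmt("depth must be >= 100")
  if (cfg$sigma_niche <= 0) stop_fmt("sigma_niche must be > 0")
  if (cfg$migration_m <= 0 || cfg$migration_m > 1)
    stop_fmt("migration_m must be in (0, 1]")
  for (g in cfg$groups) {
    need <- setdiff(c("name", "n_samples", "env_mean", "env_sd", "regime"),
                    names(g))
    if (length(need)) stop_fmt("group descriptor missing field(s): %s",
                               paste(need, collapse = ", "))
    if (!g$regime %in% c("niche", "neutral", "drifted_pools"))
      stop_fmt("unknown regime '%s'", g$regime)
  }
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a phylogeny with Brownian salinity optima
#'
#' Grows a Yule (pure-birth) tree, rescales it to root height 1, and
#' evolves a salinity optimum along its branches by Brownian motion from
#' a root value of 0.  Optima are then min-max rescaled to the fixed
#' range \[0, 35\] (a g/L-like salinity scale) so niche breadths are
#' comparable across seeds.  With `sigma_bm = 0` the rescale is
#' degenerate and all optima are set to 17.5 with a warning.
#'
#' @param n_taxa number of tips (>= 2).
#' @param sigma_bm Brownian rate.
#' @param seed RNG seed.
#' @return list with `tree` ([ape::phylo], tips `ASV_0001`, ...) and
#'   `optima` (named numeric).
#' @export
simulate_phylogeny_with_traits <- function(n_taxa, sigma_bm = 8,
                                           seed = NULL) {
  if (n_taxa < 2) stop_fmt("n_taxa must be >= 2")
  with_rng(seed, {
    tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
    h <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / h
    tr$tip.label <- sprintf("ASV_%04d", seq_len(n_taxa))
    opt <- ape::rTraitCont(tr, model = "BM", sigma = sigma_bm,
                           root.value = 0)
    rng <- range(opt)
    if (diff(rng) < 1e-12) {
      warn_fmt("trait range degenerate; all optima set to 17.5")
      opt[] <- 17.5
    } else {
      opt <- (opt - rng[1]) / diff(rng) * 35
    }
    list(tree = tr, optima = opt)
  })
}

#' Simulate lognormal metacommunity relative abundances
#'
#' @param n_taxa number of taxa.
#' @param lognormal_mu,lognormal_sigma log-abundance mean and sd;
#'   `lognormal_sigma = 0` gives a uniform pool.
#' @param seed RNG seed.
#' @return numeric vector of relative abundances summing to 1.
#' @export
simulate_metacommunity <- function(n_taxa, lognormal_mu = 0,
                                   lognormal_sigma = 2, seed = NULL) {
  if (lognormal_sigma < 0) stop_fmt("lognormal_sigma must be >= 0")
  with_rng(seed, {
    if (lognormal_sigma == 0) {
      p <- rep(1 / n_taxa, n_taxa)
    } else {
      x <- stats::rlnorm(n_taxa, lognormal_mu, lognormal_sigma)
      p <- x / sum(x)
    }
    p
  })
}

# One neutral local community: multinomial seeding from the pool, then
# Moran death-replacement dynamics with immigration m for a burn-in of
# 10 * N steps (empirically sufficient for stationarity at N <= 5000),
# then multinomial sequencing at `depth`.
.neutral_sample <- function(pool, m, N, depth) {
  init <- stats::rmultinom(1, N, pool)[, 1]
  local <- .moran_steps(as.integer(init), pool, m, as.integer(10 * N))
  stats::rmultinom(1, depth, local / N)[, 1]
}

#' Simulate a full multi-group dataset under controlled assembly regimes
#'
#' Regimes per group:
#' \describe{
#'   \item{niche}{each sample draws its environment
#'     `e ~ Normal(env_mean, env_sd)` and counts
#'     `Multinomial(depth, w)` with
#'     `w_i` proportional to `p_i * exp(-(opt_i - e)^2 / (2 sigma_niche^2))`
#'     -- deterministic salinity filtering on phylogenetically conserved
#'     optima.}
#'   \item{neutral}{a Hubbell-type local community of size `N` burned in
#'     by Moran dynamics with immigration `migration_m` from the shared
#'     regional pool, then multinomial sequencing.}
#'   \item{drifted_pools}{as neutral, but the group first receives its
#'     own Dirichlet-perturbed copy of the regional pool
#'     (concentration `dirichlet_conc * p`), creating dispersal
#'     limitation between groups.}
#' }
#' Samples are placed in group order, evenly spaced with jitter along a
#' 1-D west-east transect of `transect_km`, yielding coordinates for
#' distance-decay analysis.
#'
#' @param config a [simulation_config()].
#' @return list of class `synthetic_dataset` with elements `counts`
#'   (taxa x samples integer matrix, columns summing to `depth`), `tree`,
#'   `metadata` (sample_id, group, latitude, longitude, salinity), and
#'   `truth` (regimes, optima, pools, migration_m, environments).
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  cfg <- config
  phy <- simulate_phylogeny_with_traits(cfg$n_taxa, cfg$sigma_bm,
                                        seed_stream(cfg$seed, "tree"))
  p <- simulate_metacommunity(cfg$n_taxa, cfg$lognormal_mu,
                              cfg$lognormal_sigma,
                              seed_stream(cfg$seed, "pool"))
  names(p) <- phy$tree$tip.label
  n_total <- sum(vapply(cfg$groups, `[[`, numeric(1), "n_samples"))

  counts <- matrix(0L, cfg$n_taxa, n_total,
                   dimnames = list(phy$tree$tip.label, NULL))
  sample_id <- character(n_total)
  group <- character(n_total)
  envs <- numeric(n_total)
  group_pools <- list()

  s <- 0L
  for (gi in seq_along(cfg$groups)) {
    g <- cfg$groups[[gi]]
    e_g <- with_rng(seed_stream(cfg$seed, paste0("env_", g$name)),
                    stats::rnorm(g$n_samples, g$env_mean, g$env_sd))
    pool_g <- p
    if (g$regime == "drifted_pools") {
      pool_g <- with_rng(seed_stream(cfg$seed, paste0("pooldrift_", g$name)), {
        gam <- stats::rgamma(cfg$n_taxa, shape = cfg$dirichlet_conc * p,
                             rate = 1)
        if (sum(gam) == 0) gam <- p  # pathological concentration guard
        gam / sum(gam)
      })
      names(pool_g) <- names(p)
    }
    group_pools[[g$name]] <- pool_g
    cnt_g <- with_rng(seed_stream(cfg$seed, paste0("sampling_", g$name)), {
      vapply(seq_len(g$n_samples), function(k) {
        if (g$regime == "niche") {
          w <- p * exp(-(phy$optima - e_g[k])^2 / (2 * cfg$sigma_niche^2))
          if (sum(w) <= 0) stop_fmt("niche weights all zero for sample %d", k)
          stats::rmultinom(1, cfg$depth, w)[, 1]
        } else {
          .neutral_sample(pool_g, cfg$migration_m, cfg$community_size_N,
                          cfg$depth)
        }
      }, integer(cfg$n_taxa))
    })
    idx <- s + seq_len(g$n_samples)
    counts[, idx] <- cnt_g
    sample_id[idx] <- sprintf("%s_%02d", g$name, seq_len(g$n_samples))
    group[idx] <- g$name
    envs[idx] <- e_g
    s <- s + g$n_samples
  }
  colnames(counts) <- sample_id

  # 1-D transect west -> east at fixed latitude, even spacing + jitter
  spacing <- cfg$transect_km / n_total
  pos <- with_rng(seed_stream(cfg$seed, "space"),
                  (seq_len(n_total) - 0.5) * spacing +
                    stats::runif(n_total, -0.2, 0.2) * spacing)
  lat0 <- 39.0
  lon <- 117.5 + pos / (111.320 * cos(lat0 * pi / 180))
  metadata <- data.frame(sample_id = sample_id, group = group,
                         latitude = lat0, longitude = lon,
                         salinity = envs, stringsAsFactors = FALSE)
  rownames(metadata) <- sample_id

  out <- list(counts = counts, tree = phy$tree, metadata = metadata,
              truth = list(
                regimes = stats::setNames(
                  vapply(cfg$groups, `[[`, character(1), "regime"),
                  vapply(cfg$groups, `[[`, character(1), "name")),
                optima = phy$optima, pool = p, group_pools = group_pools,
                migration_m = cfg$migration_m, env = envs,
                config = unclass(cfg)))
  class(out) <- "synthetic_dataset"
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic dataset: %d taxa x %d samples, groups: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$metadata$group), collapse = ", ")))
  cat(sprintf("regimes: %s\n",
              paste(sprintf("%s=%s", names(x$truth$regimes), x$truth$regimes),
                    collapse = ", ")))
  invisible(x)
}

#' Write a synthetic dataset to standard files
#'
#' Emits counts TSV, newick tree, metadata TSV and a `truth.json`
#' sidecar into a directory.
#' @param x a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synthetic_dataset <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(x$counts, file.path(dir, "counts.tsv"))
  write_tree_newick(x$tree, file.path(dir, "tree.nwk"))
  write_sample_metadata(x$metadata, file.path(dir, "metadata.tsv"))
  truth <- x$truth
  truth$optima <- as.list(truth$optima)
  truth$pool <- as.list(truth$pool)
  truth$group_pools <- lapply(truth$group_pools, as.list)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
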