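# Pipeline orchestration: simulate -> diversity -> assembly -> network
# as one reproducible run driven by a single config and master seed,
# with a machine-readable manifest of outputs and checksums.

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order on either supplied input files
#' (`counts`, `tree`, `metadata` paths) or a simulated dataset
#' (`simulation` config).  Inputs are cross-validated up front (samples
#' present in metadata, taxa present in the tree); on failure the run
#' aborts before any stage writes output, listing every inconsistency.
#' All per-stage seeds derive from the master seed via named streams, so
#' an identical config gives identical output checksums.
#'
#' @param config a list (or YAML file path) with fields:
#'   \describe{
#'     \item{counts, tree, metadata}{input file paths, or}
#'     \item{simulation}{arguments for [simulation_config()]}
#'     \item{stages}{character subset of `c("simulate", "diversity",
#'       "assembly", "network")`}
#'     \item{out}{output directory}
#'     \item{seed}{master seed}
#'     \item{depth}{optional rarefaction depth}
#'     \item{n_perm, n_null, top_n, rho_threshold, alpha, adjust,
#'       fractions, n_rep}{stage parameters}
#'   }
#' @return the run manifest (list of class `pipeline_manifest`), also
#'   written as `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  out_dir <- cfg$out %||% stop_fmt("config needs an 'out' directory")
  seed <- cfg$seed %||% stop_fmt("config needs a 'seed'")
  stages <- cfg$stages %||% c("simulate", "diversity", "assembly", "network")
  bad <- setdiff(stages, c("simulate", "diversity", "assembly", "network"))
  if (length(bad)) stop_fmt("unknown stage(s): %s", paste(bad, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!length(stages)) {
    manifest <- list(package_version = as.character(
                       utils::packageVersion("ecoassembly")),
                     seed = seed, stages = list(),
                     warnings = character(0))
    class(manifest) <- "pipeline_manifest"
    jsonlite::write_json(unclass(manifest),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    return(manifest)
  }

  # --- inputs -------------------------------------------------------------
  if ("simulate" %in% stages) {
    sim_args <- cfg$simulation %||% list()
    sim_args$seed <- sim_args$seed %||% seed_stream(seed, "simulate")
    ds <- simulate_dataset(do.call(simulation_config, sim_args))
    counts <- ds$counts; tree <- ds$tree; metadata <- ds$metadata
  } else {
    for (f in c("counts", "tree", "metadata"))
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
        stop_fmt("input file for '%s' missing or not found", f)
    counts <- read_count_table(cfg$counts)
    tree <- read_tree_newick(cfg$tree)
    metadata <- read_sample_metadata(cfg$metadata)
    ds <- NULL
  }

  # --- fail-fast cross-validation ----------------------------------------
  problems <- character(0)
  miss_md <- setdiff(colnames(counts), rownames(metadata))
  if (length(miss_md))
    problems <- c(problems, sprintf("samples absent from metadata: %s",
                                    paste(miss_md, collapse = ", ")))
  miss_tip <- setdiff(rownames(counts), tree$tip.label)
  if (length(miss_tip))
    problems <- c(problems, sprintf("taxa absent from tree: %s",
                                    paste(utils::head(miss_tip, 10),
                                          collapse = ", ")))
  if (length(problems))
    stop_fmt("input cross-validation failed:\n  - %s",
             paste(problems, collapse = "\n  - "))
  metadata <- metadata[colnames(counts), , drop = FALSE]
  groups <- metadata$group

  manifest <- list(package_version = as.character(
                     utils::packageVersion("ecoassembly")),
                   seed = seed, stages = list(), warnings = character(0))
  note <- function(stage, files, params) {
    manifest$stages[[stage]] <<- list(
      params = params,
      outputs = lapply(stats::setNames(files, basename(files)),
                       function(f) unname(tools::md5sum(f))))
  }
  log_event <- function(stage, msg)
    message(sprintf("[%s] %s", stage, msg))

  if ("simulate" %in% stages) {
    log_event("simulate", sprintf("%d taxa x %d samples",
                                  nrow(counts), ncol(counts)))
    write_synthetic_dataset(ds, out_dir)
    files <- file.path(out_dir, c("counts.tsv", "tree.nwk",
                                  "metadata.tsv", "truth.json"))
    note("simulate", files, list(seed = seed))
  }

  if (!is.null(cfg$depth)) {
    counts <- rarefy(counts, cfg$depth, seed = seed_stream(seed, "rarefy"))
  }

  if ("diversity" %in% stages) {
    n_perm <- cfg$n_perm %||% 999
    log_event("diversity", sprintf("n_perm = %d", n_perm))
    alpha_df <- data.frame(sample_id = colnames(counts),
                           shannon = shannon(counts),
                           faith_pd = faith_pd(counts, tree),
                           stringsAsFactors = FALSE)
    bc <- bray_curtis(counts)
    pc <- pcoa(bc, k = 2)
    pm <- permanova(bc, groups, n_perm = n_perm,
                    seed = seed_stream(seed, "permanova"))
    files <- file.path(out_dir, c("alpha_diversity.tsv", "bray_curtis.tsv",
                                  "pcoa.tsv", "permanova.tsv"))
    write_outputs(alpha_df, files[1])
    write_distance_matrix(bc, files[2])
    write_outputs(data.frame(sample_id = rownames(pc$points), pc$points),
                  files[3])
    write_outputs(data.frame(pseudo_F = pm$pseudo_F, R2 = pm$R2, p = pm$p),
                  files[4])
    if (!is.null(metadata$latitude) && !anyNA(metadata$latitude)) {
      dd <- distance_decay(counts, metadata, n_perm = n_perm,
                           seed = seed_stream(seed, "decay"))
      f <- file.path(out_dir, "distance_decay.tsv")
      write_outputs(data.frame(mantel_r = dd$mantel$r, mantel_p = dd$mantel$p,
                               slope = dd$slope, intercept = dd$intercept,
                               r_squared = dd$r_squared), f)
      files <- c(files, f)
    }
    note("diversity", files, list(n_perm = n_perm))
  }

  if ("assembly" %in% stages) {
    n_null <- cfg$n_null %||% 999
    log_event("assembly", sprintf("n_null = %d", n_null))
    ncm <- fit_ncm(counts)
    bnti <- compute_bnti(counts, tree, n_null = n_null,
                         seed = seed_stream(seed, "bnti"))
    rc <- compute_rcbray(counts, n_null = n_null,
                         seed = seed_stream(seed, "rcbray"))
    part <- partition_processes(bnti, rc, groups)
    files <- file.path(out_dir, c("ncm_fit.tsv", "bnti.tsv", "rcbray.tsv",
                                  "partition.tsv"))
    ncm_df <- cbind(ncm$taxa,
                    data.frame(m = ncm$m, N = ncm$N, R2 = ncm$R2))
    write_outputs(ncm_df, files[1])
    write_outputs(`diag<-`(bnti, 0), files[2])
    write_outputs(`diag<-`(rc, 0), files[3])
    write_outputs(part, files[4])
    note("assembly", files, list(n_null = n_null))
  }

  if ("network" %in% stages) {
    top_n <- cfg$top_n %||% 500
    log_event("network", sprintf("top_n = %d", top_n))
    net <- build_network(counts, top_n = top_n,
                         rho_threshold = cfg$rho_threshold %||% 0.6,
                         alpha = cfg$alpha %||% 0.05,
                         adjust = cfg$adjust %||% "bh")
    top <- topology_report(net, n_random = cfg$n_random %||% 100,
                           seed = seed_stream(seed, "topology"))
    roles <- zi_pi_roles(net, top$membership)
    rob <- rbind(robustness_curve(net, "random",
                                  fractions = cfg$fractions %||%
                                    seq(0, 1, by = 0.1),
                                  n_rep = cfg$n_rep %||% 50,
                                  seed = seed_stream(seed, "rob_random")),
                 robustness_curve(net, "targeted",
                                  fractions = cfg$fractions %||%
                                    seq(0, 1, by = 0.1),
                                  n_rep = cfg$n_rep %||% 50,
                                  seed = seed_stream(seed, "rob_targeted"),
                                  roles = roles))
    files <- file.path(out_dir, c("network.graphml", "edges.tsv",
                                  "topology_report.tsv", "node_roles.tsv",
                                  "stability_curves.tsv"))
    write_outputs(net, files[1], "graphml")
    write_outputs(net, files[2], "edgelist")
    write_outputs(as.data.frame(top), files[3])
    write_outputs(as.data.frame(roles), files[4])
    write_outputs(as.data.frame(rob), files[5])
    note("network", files, list(top_n = top_n))
  }

  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_json, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest$config_hash <- unname(tools::md5sum(cfg_json))
  class(manifest) <- "pipeline_manifest"
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat(sprintf("pipeline run (ecoassembly %s, seed %s)\n",
              x$package_version, x$seed))
  for (s in names(x$stages))
    cat(sprintf("  %s: %d output file(s)\n", s, length(x$stages[[s]]$outputs)))
  invisible(x)
}
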