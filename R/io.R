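# Readers, writers and validation for the standard formats the pipeline
# touches: count table TSV / BIOM(JSON), newick trees, metadata TSV,
# square distance-matrix TSV, network GraphML / edge lists.
#
# Conventions: count tables are taxa-as-rows, samples-as-columns; a
# transposed table (header cell naming samples) is rejected with a hint,
# never silently transposed.  All writers emit UTF-8, tab-delimited text
# with '.' decimals and reals at 6 significant digits, so identical
# inputs give byte-identical files.

#' Validate a count table
#'
#' Checks the invariants every downstream function relies on:
#' non-negative integer counts, unique taxon and sample ids, at least one
#' taxon and two samples, and no empty (all-zero) sample column.
#'
#' @param counts integer matrix, taxa x samples, with dimnames.
#' @param allow_zero_columns keep all-zero sample columns (used
#'   internally when sub-setting by group).
#' @return the validated matrix, invisibly.
#' @export
validate_count_table <- function(counts, allow_zero_columns = FALSE) {
  if (!is.matrix(counts)) stop_fmt("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_fmt("counts must have taxon row names and sample column names")
  if (nrow(counts) < 1 || ncol(counts) < 2)
    stop_fmt("count table needs >= 1 taxon and >= 2 samples")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup)) stop_fmt("duplicated taxon id(s): %s",
                            paste(unique(dup), collapse = ", "))
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup)) stop_fmt("duplicated sample id(s): %s",
                            paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop_fmt("negative or non-finite count at [%s]",
             paste(sprintf("%s,%s", rownames(counts)[bad[, 1]],
                           colnames(counts)[bad[, 2]])[seq_len(min(5, nrow(bad)))],
                   collapse = "; "))
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
    stop_fmt("non-integer count at [%s]",
             paste(sprintf("%s,%s", rownames(counts)[bad[, 1]],
                           colnames(counts)[bad[, 2]])[seq_len(min(5, nrow(bad)))],
                   collapse = "; "))
  }
  if (!allow_zero_columns) {
    z <- colnames(counts)[colSums(counts) == 0]
    if (length(z)) stop_fmt("sample(s) with zero total counts: %s",
                            paste(z, collapse = ", "))
  }
  invisible(counts)
}

#' Read a taxa-by-samples count table
#'
#' @param path file path.
#' @param dialect `"tsv"` (first column taxon ids, header row sample ids,
#'   optional `taxonomy` column) or `"biom-json"` (JSON-dialect BIOM,
#'   read via the biomformat package).
#' @return integer matrix (taxa x samples) with attributes `taxonomy`
#'   (character vector or `NULL`) and `report` (list with `n_taxa`,
#'   `n_samples`, `total_reads`).
#' @export
read_count_table <- function(path, dialect = c("tsv", "biom-json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  taxonomy <- NULL
  if (dialect == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop_fmt("count table needs an id column and >= 1 sample")
    corner <- tolower(names(df)[1])
    if (grepl("^sample", corner))
      stop_fmt(paste0("header suggests samples as rows ('%s'); count tables",
                      " must be taxa x samples - transpose the input"),
               names(df)[1])
    ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
    tax_col <- which(tolower(names(df)) == "taxonomy")
    if (length(tax_col)) {
      taxonomy <- as.character(df[[tax_col[1]]])
      names(taxonomy) <- ids
      df <- df[, -tax_col, drop = FALSE]
    }
    m <- as.matrix(df)
    if (!is.numeric(m)) stop_fmt("non-numeric cells in count table")
    rownames(m) <- ids
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop_fmt("the biomformat package is required for dialect 'biom-json'")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
  }
  storage.mode(m) <- "double"
  validate_count_table(m)
  storage.mode(m) <- "integer"
  attr(m, "taxonomy") <- taxonomy
  attr(m, "report") <- list(n_taxa = nrow(m), n_samples = ncol(m),
                            total_reads = sum(m))
  m
}

#' Write a count table as TSV
#'
#' @param counts taxa x samples matrix.
#' @param path output path.
#' @export
write_count_table <- function(counts, path) {
  validate_count_table(counts)
  df <- data.frame(taxon_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  tax <- attr(counts, "taxonomy")
  if (!is.null(tax)) df$taxonomy <- tax[rownames(counts)]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a rooted newick tree with branch lengths
#'
#' Branch lengths are required (zero allowed) because all phylogenetic
#' metrics in the package (Faith's PD, beta-MNTD, betaNTI) are
#' branch-length based.
#'
#' @param path newick file.
#' @return an [ape::phylo] tree.
#' @export
read_tree_newick <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop_fmt("newick parse error: %s",
                                              conditionMessage(e)))
  if (is.null(tr)) stop_fmt("newick parse error in %s", path)
  validate_tree(tr)
  tr
}

#' Validate a phylogenetic tree
#' @param tr an [ape::phylo] object.
#' @return the tree, invisibly.
#' @export
validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop_fmt("tree must be an ape 'phylo' object")
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
      anyNA(tr$edge.length))
    stop_fmt("tree has missing branch lengths; lengths are required")
  if (any(tr$edge.length < 0)) stop_fmt("tree has negative branch lengths")
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup)) stop_fmt("duplicated tip label(s): %s",
                            paste(unique(dup), collapse = ", "))
  invisible(tr)
}

#' Write a tree as newick
#' @param tr an [ape::phylo] tree.
#' @param path output path.
#' @export
write_tree_newick <- function(tr, path) {
  validate_tree(tr)
  ape::write.tree(tr, file = path, digits = 15)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Requires columns `sample_id` and `group`; `latitude`/`longitude`
#' (decimal degrees) and any further numeric environment columns are
#' optional.  Environment columns are coerced to numeric; unparseable or
#' "NA" cells become `NA` and are flagged in the `missing_env` attribute
#' rather than failing.
#'
#' @param path TSV file.
#' @return data.frame with row names = sample ids.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- setdiff(c("sample_id", "group"), names(df))
  if (length(need)) stop_fmt("metadata missing required column(s): %s",
                             paste(need, collapse = ", "))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop_fmt("duplicated sample id(s): %s",
                            paste(unique(dup), collapse = ", "))
  rownames(df) <- df$sample_id
  for (cc in c("latitude", "longitude")) {
    if (cc %in% names(df)) {
      df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
      lim <- if (cc == "latitude") 90 else 180
      bad <- df$sample_id[!is.na(df[[cc]]) & abs(df[[cc]]) > lim]
      if (length(bad))
        stop_fmt("%s out of range [-%d, %d] for sample(s): %s",
                 cc, lim, lim, paste(bad, collapse = ", "))
    }
  }
  env_cols <- setdiff(names(df), c("sample_id", "group",
                                   "latitude", "longitude"))
  missing_env <- list()
  for (cc in env_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (all(is.na(v)) && !all(is.na(df[[cc]]) | df[[cc]] == "NA")) next
    miss <- df$sample_id[is.na(v)]
    if (length(miss)) missing_env[[cc]] <- miss
    df[[cc]] <- v
  }
  attr(df, "missing_env") <- missing_env
  df
}

#' Write sample metadata as TSV
#' @param metadata data.frame as returned by [read_sample_metadata()].
#' @param path output path.
#' @export
write_sample_metadata <- function(metadata, path) {
  df <- metadata
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_real)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a square distance matrix TSV
#'
#' @param path file path.
#' @return symmetric numeric matrix with ids as dimnames.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  as_square_dist(m, sprintf("distance matrix in %s", path))
}

#' @rdname read_distance_matrix
#' @param d symmetric matrix.
#' @export
write_distance_matrix <- function(d, path) {
  d <- as_square_dist(d)
  df <- data.frame(id = rownames(d),
                   apply(d, 2, fmt_real),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a result object to file
#'
#' Dispatches on the result type: co-occurrence networks support
#' `"graphml"` and `"edgelist"`, tabular results support `"tsv"`.
#' Unsupported pairings are an error.  Rows whose order carries no
#' meaning are sorted lexicographically so output is byte-stable.
#'
#' @param x a result object (network, partition, data.frame, matrix).
#' @param path output path.
#' @param format one of `"tsv"`, `"graphml"`, `"edgelist"`.
#' @export
write_outputs <- function(x, path, format = "tsv") {
  UseMethod("write_outputs")
}

#' @export
write_outputs.cooccurrence_network <- function(x, path, format = "tsv") {
  if (format == "graphml") {
    igraph::write_graph(x$graph, path, format = "graphml")
  } else if (format == "edgelist") {
    e <- x$edges[order(x$edges$source, x$edges$target), , drop = FALSE]
    e$rho <- fmt_real(e$rho)
    utils::write.table(e[, c("source", "target", "rho")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  } else {
    stop_fmt("networks support formats 'graphml' and 'edgelist', not '%s'",
             format)
  }
  invisible(path)
}

#' @export
write_outputs.assembly_partition <- function(x, path, format = "tsv") {
  if (format != "tsv") stop_fmt("partitions only support format 'tsv'")
  df <- x$fractions
  df$fraction <- fmt_real(df$fraction)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
write_outputs.data.frame <- function(x, path, format = "tsv") {
  if (format != "tsv") stop_fmt("tables only support format 'tsv'")
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], fmt_real)
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
write_outputs.matrix <- function(x, path, format = "tsv") {
  if (format != "tsv") stop_fmt("matrices only support format 'tsv'")
  df <- data.frame(id = rownames(x) %||% seq_len(nrow(x)),
                   apply(x, 2, fmt_real),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
write_outputs.default <- function(x, path, format = "tsv") {
  stop_fmt("no writer for objects of class '%s'", class(x)[1])
}
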