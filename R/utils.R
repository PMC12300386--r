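# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded package functions
#' do not perturb the global random stream.
#' @noRd
with_rng <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Derive a named child seed from a master seed
#'
#' Each simulation component (tree, traits, environment, sampling, ...)
#' draws from its own stream so that components are individually
#' reproducible.  The derived seed always fits in a 32-bit integer.
#' @param seed master seed (integer).
#' @param name stream name.
#' @return an integer seed.
#' @export
seed_stream <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  ch <- utf8ToInt(name)
  h <- sum(ch * (131 ^ ((seq_along(ch) - 1) %% 5)))
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}

# Format a numeric for bit-stable TSV output: 6 significant digits,
# '.' decimal separator, no scientific notation surprises.
fmt_real <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}

# Upper-triangle (i < j) values of a square matrix, in column-major order.
upper_vals <- function(m) m[upper.tri(m)]

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

# Check that a square dissimilarity input is usable; returns a plain
# symmetric matrix with ids as dimnames.
as_square_dist <- function(d, what = "distance matrix") {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop_fmt("%s must be square", what)
  if (max(abs(d - t(d))) > 1e-8) stop_fmt("%s is not symmetric", what)
  if (any(diag(d) != 0)) stop_fmt("%s has a non-zero diagonal", what)
  if (any(d < 0)) stop_fmt("%s has negative entries", what)
  d
}
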