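# Sloan neutral community model: predicts a taxon's occurrence
# frequency across samples from its mean regional relative abundance,
# the community size N and the immigration probability m.  A good fit
# (R2 near 1) indicates neutral/stochastic assembly; R2 near or below
# zero indicates deterministic structuring.

#' Fit the Sloan neutral community model
#'
#' With `N` the mean reads per sample, detection limit `d = 1/N` and
#' `p_i` the mean relative abundance of taxon i, the model predicts the
#' occurrence frequency
#' `F_i = 1 - I(d; N m p_i, N m (1 - p_i))`
#' where `I` is the regularized incomplete beta CDF ([stats::pbeta]).
#' The single free parameter `m` is estimated by bounded least squares on
#' the observed frequencies (multi-start grid over `m` in 1e-4..1
#' followed by local optimisation); `method = "likelihood"` minimises the
#' binomial negative log-likelihood instead.  R2 = 1 - SSE/SST may be
#' negative.  95% Wilson score intervals around the prediction (with n =
#' number of samples) classify each taxon as above/within/below.
#'
#' @param counts taxa x samples matrix (>= 5 samples).
#' @param method `"sse"` (default) or `"likelihood"`.
#' @return object of class `ncm_fit`: `m`, `N`, `R2`, `n_samples`, and a
#'   per-taxon data.frame `taxa` (p, freq_obs, freq_pred, ci_lower,
#'   ci_upper, class).
#' @export
fit_ncm <- function(counts, method = c("sse", "likelihood")) {
  method <- match.arg(method)
  if (ncol(counts) < 5) stop_fmt("NCM fit needs >= 5 samples")
  n_samp <- ncol(counts)
  N <- mean(colSums(counts))
  d <- 1 / N
  rel <- sweep(counts, 2, colSums(counts), "/")
  p <- rowMeans(rel)
  freq <- rowMeans(counts > 0)
  keep <- p > 0
  p <- p[keep]; freq <- freq[keep]

  degenerate <- FALSE
  sst <- sum((freq - mean(freq))^2)
  if (sst == 0) {
    warn_fmt("no variation in occurrence frequency; degenerate NCM fit")
    degenerate <- TRUE
  }

  pred_fun <- function(m) 1 - stats::pbeta(d, N * m * p, N * m * (1 - p))
  objective <- if (method == "sse") {
    function(m) sum((pred_fun(m) - freq)^2)
  } else {
    function(m) {
      f <- pmin(pmax(pred_fun(m), 1e-12), 1 - 1e-12)
      -sum(n_samp * (freq * log(f) + (1 - freq) * log(1 - f)))
    }
  }
  grid <- 10^seq(-4, 0, length.out = 25)
  vals <- vapply(grid, objective, numeric(1))
  i0 <- which.min(vals)
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  opt <- stats::optimize(objective, interval = c(lo, hi))
  m_hat <- min(max(opt$minimum, 1e-6), 1)

  f_hat <- pred_fun(m_hat)
  sse <- sum((f_hat - freq)^2)
  r2 <- if (degenerate) NA_real_ else 1 - sse / sst

  z <- stats::qnorm(0.975)
  den <- 1 + z^2 / n_samp
  ctr <- (f_hat + z^2 / (2 * n_samp)) / den
  half <- z * sqrt(f_hat * (1 - f_hat) / n_samp + z^2 / (4 * n_samp^2)) / den
  ci_lo <- pmax(ctr - half, 0)
  ci_hi <- pmin(ctr + half, 1)
  cls <- ifelse(freq > ci_hi, "above", ifelse(freq < ci_lo, "below", "within"))

  out <- list(m = m_hat, N = N, R2 = r2, n_samples = n_samp,
              method = method, degenerate = degenerate,
              taxa = data.frame(taxon = names(p), p = p, freq_obs = freq,
                                freq_pred = f_hat, ci_lower = ci_lo,
                                ci_upper = ci_hi, class = cls,
                                stringsAsFactors = FALSE,
                                row.names = NULL))
  class(out) <- "ncm_fit"
  out
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Sloan neutral community model (%s fit)\n", x$method))
  cat(sprintf("  N = %.1f, m = %.4g, R2 = %s, %d taxa, %d samples\n",
              x$N, x$m, if (is.na(x$R2)) "NA" else sprintf("%.3f", x$R2),
              nrow(x$taxa), x$n_samples))
  cat(sprintf("  taxa above/within/below prediction: %d/%d/%d\n",
              sum(x$taxa$class == "above"), sum(x$taxa$class == "within"),
              sum(x$taxa$class == "below")))
  invisible(x)
}

#' @export
summary.ncm_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.ncm_fit <- function(object, ...) {
  c(m = object$m, N = object$N, R2 = object$R2)
}

#' Predicted occurrence frequency for given mean relative abundances
#' @param object an `ncm_fit`.
#' @param newdata numeric vector of mean relative abundances (defaults
#'   to the fitted taxa).
#' @param ... unused.
#' @export
predict.ncm_fit <- function(object, newdata = NULL, ...) {
  p <- newdata %||% object$taxa$p
  d <- 1 / object$N
  1 - stats::pbeta(d, object$N * object$m * p,
                   object$N * object$m * (1 - p))
}

#' Occurrence-frequency plot for a fitted NCM
#' @param x an `ncm_fit`.
#' @param ... passed to [plot()].
#' @export
plot.ncm_fit <- function(x, ...) {
  tx <- x$taxa[order(x$taxa$p), ]
  cols <- c(above = "darkgreen", within = "grey40", below = "firebrick")
  plot(log10(tx$p), tx$freq_obs, pch = 16, cex = 0.6,
       col = cols[tx$class],
       xlab = "log10 mean relative abundance",
       ylab = "occurrence frequency", ...)
  graphics::lines(log10(tx$p), tx$freq_pred, col = "blue", lwd = 2)
  graphics::lines(log10(tx$p), tx$ci_lower, col = "blue", lty = 2)
  graphics::lines(log10(tx$p), tx$ci_upper, col = "blue", lty = 2)
  invisible(x)
}
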