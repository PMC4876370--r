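#' Split-chain potential scale reduction factor
#'
#' Gelman-Rubin convergence diagnostic with chain splitting: each chain is
#' halved, and the between- to within-half-chain variance ratio is
#' computed over the resulting `2 * chains` sequences. A value close to 1
#' indicates that lengthening the chains is not expected to change the
#' estimate.
#'
#' @param draws A matrix with one column per chain (rows are retained
#'   iterations), or a list of equal-length numeric vectors.
#' @return A single number, >= 0 and approximately 1 at convergence.
#' @export
rhat <- function(draws) {
  if (is.list(draws) && !is.matrix(draws))
    draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  n <- nrow(draws); ch <- ncol(draws)
  if (ch < 2) stop("at least 2 chains are required")
  if (n < 4) stop("at least 4 retained draws per chain are required")
  half <- n %/% 2L
  splits <- vector("list", 2L * ch)
  for (j in seq_len(ch)) {
    splits[[2 * j - 1]] <- draws[seq_len(half), j]
    splits[[2 * j]] <- draws[(n - half + 1):n, j]
  }
  m <- length(splits); len <- half
  means <- vapply(splits, mean, 0)
  vars <- vapply(splits, stats::var, 0)
  W <- mean(vars)
  B <- len * stats::var(means)
  if (W <= 0) {
    if (B <= 0) stop("degenerate chains")
    return(Inf)
  }
  var_plus <- (len - 1) / len * W + B / len
  sqrt(var_plus / W)
}

# Rhat for every column of per-chain draw matrices (list of chains, each
# an iterations x P matrix). Returns a named numeric vector.
rhat_all <- function(chains, names = NULL) {
  P <- ncol(chains[[1]])
  out <- vapply(seq_len(P), function(p) {
    tryCatch(rhat(do.call(cbind, lapply(chains, function(m) m[, p]))),
             error = function(e) NA_real_)  # pinned parameters have no Rhat
  }, 0)
  if (!is.null(names)) names(out) <- names
  out
}

#' Tabulate potential-scale-reduction bookkeeping
#'
#' Summarizes a collection of Rhat values the way MCMC convergence tables
#' are usually reported: the mean Rhat and the percentage of parameters
#' whose Rhat exceeds each threshold.
#'
#' @param rhats Numeric vector of Rhat values (pooled over parameters and
#'   datasets).
#' @param thresholds Increasing thresholds; default `c(1.05, 1.1, 1.5, 1.7)`.
#' @return A one-row data frame: `mean_rhat`, then `pct_above_<threshold>`
#'   columns in percent.
#' @export
rhat_table <- function(rhats, thresholds = c(1.05, 1.1, 1.5, 1.7)) {
  rhats <- rhats[is.finite(rhats)]
  out <- data.frame(mean_rhat = mean(rhats))
  for (th in thresholds)
    out[[sprintf("pct_above_%g", th)]] <- 100 * mean(rhats > th)
  out
}
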