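# Generation of multilevel AR(1) panels: individual series
#   y[t] = mu_n + phi_n * (y[t-1] - mu_n) + e[t],   e[t] ~ N(0, sigma_e)
# with individual autocorrelations phi_n drawn from a normal distribution
# truncated and renormalized on (-1, 1) and individual means
# mu_n = gamma00 + U0_n, U0_n ~ N(0, sigma_u0).

#' Define one cell of the simulation design
#'
#' A condition bundles the generator settings for one cell of the fully
#' crossed design: series length `T`, number of individuals `N`, the mean
#' `gamma01` and between-person SD `sigma_u1` of the individual
#' autocorrelations, plus the fixed settings (population intercept
#' `gamma00`, between-person intercept SD `sigma_u0`, innovation SD
#' `sigma_e`).
#'
#' @param T Integer number of time points per series (at least 2).
#' @param N Integer number of individuals (at least 1).
#' @param gamma01 Population mean of the individual autocorrelations,
#'   strictly inside (-1, 1).
#' @param sigma_u1 Between-person SD of the autocorrelation, positive.
#' @param gamma00 Population intercept; default 0.
#' @param sigma_u0 Between-person SD of the individual means; default 1.
#' @param sigma_e Innovation SD; default 1.
#' @return An object of class `mlar1_condition` (a named list).
#' @examples
#' cond <- mlar1_condition(T = 10, N = 10, gamma01 = 0.3, sigma_u1 = 0.25)
#' @export
mlar1_condition <- function(T, N, gamma01, sigma_u1,
                            gamma00 = 0, sigma_u0 = 1, sigma_e = 1) {
  T <- as.integer(T); N <- as.integer(N)
  if (T < 2L) stop("T must be at least 2")
  if (N < 1L) stop("N must be at least 1")
  if (!is.finite(gamma01) || abs(gamma01) >= 1)
    stop("gamma01 must lie strictly inside (-1, 1)")
  if (!is.finite(sigma_u1) || sigma_u1 <= 0)
    stop("sigma_u1 must be positive")
  if (sigma_u0 < 0) stop("sigma_u0 must be non-negative")
  if (sigma_e <= 0) stop("sigma_e must be positive")
  structure(
    list(T = T, N = N, gamma01 = gamma01, sigma_u1 = sigma_u1,
         gamma00 = gamma00, sigma_u0 = sigma_u0, sigma_e = sigma_e),
    class = "mlar1_condition"
  )
}

#' @export
print.mlar1_condition <- function(x, ...) {
  cat(sprintf(
    "Multilevel AR(1) condition: T = %d, N = %d, gamma01 = %g, sigma_u1 = %g\n",
    x$T, x$N, x$gamma01, x$sigma_u1))
  cat(sprintf("  gamma00 = %g, sigma_u0 = %g, sigma_e = %g\n",
              x$gamma00, x$sigma_u0, x$sigma_e))
  invisible(x)
}

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. seed = NULL means "use the ambient RNG stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Draw individual autocorrelations from a truncated normal
#'
#' Samples `n` values from the normal distribution with mean `gamma01` and
#' SD `sigma_u1`, truncated to the stationary region (-1, 1) with its
#' density renormalized over that interval. Sampling uses the
#' inverse-CDF method, so it is exact (no rejection loop) and consumes a
#' fixed number of uniforms per draw.
#'
#' @param gamma01 Mean of the untruncated normal, strictly inside (-1, 1).
#' @param sigma_u1 SD of the untruncated normal, positive.
#' @param n Number of draws.
#' @param seed Optional integer seed; if given the caller's RNG state is
#'   left untouched.
#' @return Numeric vector of `n` values, all strictly inside (-1, 1).
#' @export
sample_phi <- function(gamma01, sigma_u1, n, seed = NULL) {
  if (!is.finite(gamma01) || abs(gamma01) >= 1)
    stop("gamma01 must lie strictly inside (-1, 1)")
  if (!is.finite(sigma_u1) || sigma_u1 <= 0)
    stop("sigma_u1 must be positive")
  if (n < 1) stop("n must be at least 1")
  with_seed(seed, {
    p_lo <- stats::pnorm(-1, gamma01, sigma_u1)
    p_hi <- stats::pnorm(1, gamma01, sigma_u1)
    u <- stats::runif(n, p_lo, p_hi)
    phi <- stats::qnorm(u, gamma01, sigma_u1)
    eps <- 1e-12
    pmin(pmax(phi, -1 + eps), 1 - eps)
  })
}

# log-density of the (-1,1)-truncated N(gamma01, sigma_u1); used by tests
# and by the hierarchical samplers.
dtruncphi <- function(phi, gamma01, sigma_u1, log = FALSE) {
  lz <- log(stats::pnorm(1, gamma01, sigma_u1) -
              stats::pnorm(-1, gamma01, sigma_u1))
  ld <- ifelse(abs(phi) < 1,
               stats::dnorm(phi, gamma01, sigma_u1, log = TRUE) - lz,
               -Inf)
  if (log) ld else exp(ld)
}

#' Simulate a single stationary AR(1) series
#'
#' The first observation is drawn from the stationary distribution
#' `N(mu, sigma_e^2 / (1 - phi^2))`; later observations follow the
#' recursion `y[t] = mu + phi * (y[t-1] - mu) + e[t]` with
#' `e[t] ~ N(0, sigma_e)`. No burn-in is needed: the series is exactly
#' stationary from the first observation.
#'
#' @param mu Individual mean of the series.
#' @param phi Autocorrelation, strictly inside (-1, 1).
#' @param sigma_e Innovation SD, positive.
#' @param T Number of time points (at least 2).
#' @param seed Optional integer seed.
#' @param standardize_innovations If `TRUE`, the realized innovations
#'   `e[2..T]` are recentered and rescaled so their sample mean and SD are
#'   exactly 0 and `sigma_e` before the recursion is applied. Default
#'   `FALSE`: innovations are plain `N(0, sigma_e)` draws.
#' @return Numeric vector of length `T`.
#' @export
generate_series <- function(mu, phi, sigma_e, T, seed = NULL,
                            standardize_innovations = FALSE) {
  if (!is.finite(phi) || abs(phi) >= 1)
    stop("phi must lie strictly inside (-1, 1) (stationarity)")
  if (sigma_e <= 0) stop("sigma_e must be positive")
  T <- as.integer(T)
  if (T < 2L) stop("T must be at least 2")
  with_seed(seed, {
    z1 <- stats::rnorm(1, 0, sigma_e / sqrt(1 - phi^2))
    e <- stats::rnorm(T - 1L, 0, sigma_e)
    if (standardize_innovations && T > 2L)
      e <- (e - mean(e)) / stats::sd(e) * sigma_e
    z <- as.numeric(stats::filter(e, phi, method = "recursive", init = z1))
    c(mu + z1, mu + z)
  })
}

#' Generate a full multilevel AR(1) panel
#'
#' Draws the individual autocorrelations with [sample_phi()], the
#' individual means as `gamma00 + U0_n` with `U0_n ~ N(0, sigma_u0)`, and
#' then `N` independent series with [generate_series()]. The true
#' individual parameters are retained alongside the scores so that
#' estimator bias can be measured. A fixed `(condition, seed)` pair yields
#' a bit-identical panel on every call.
#'
#' @param condition An [mlar1_condition()].
#' @param seed Integer seed for the panel.
#' @param standardize_innovations Passed to [generate_series()].
#' @return An object of class `mlar1_panel`: list with `scores` (a
#'   `T x N` matrix, one column per individual), `phi_true`, `mu_true`,
#'   `condition` and `seed`.
#' @export
generate_panel <- function(condition, seed = NULL,
                           standardize_innovations = FALSE) {
  stopifnot(inherits(condition, "mlar1_condition"))
  with_seed(seed, {
    N <- condition$N; T <- condition$T
    phi <- sample_phi(condition$gamma01, condition$sigma_u1, N)
    u0 <- stats::rnorm(N, 0, condition$sigma_u0)
    mu <- condition$gamma00 + u0
    scores <- matrix(NA_real_, nrow = T, ncol = N)
    for (n in seq_len(N)) {
      scores[, n] <- generate_series(
        mu[n], phi[n], condition$sigma_e, T,
        standardize_innovations = standardize_innovations)
    }
    structure(
      list(scores = scores, phi_true = phi, mu_true = mu,
           condition = condition,
           seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
      class = "mlar1_panel")
  })
}

#' @export
print.mlar1_panel <- function(x, ...) {
  cat(sprintf("Multilevel AR(1) panel: N = %d individuals x T = %d time points\n",
              ncol(x$scores), nrow(x$scores)))
  cat(sprintf("  true phi range [%.3f, %.3f]; seed %s\n",
              min(x$phi_true), max(x$phi_true),
              ifelse(is.na(x$seed), "<ambient>", x$seed)))
  invisible(x)
}
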