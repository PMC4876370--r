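# Random-model (REML) estimator. The lag-regression form of the
# multilevel AR(1) model is a linear mixed model: for t = 2..T,
#   y[t, n] = beta0 + beta1 * y[t-1, n] + u0_n + u1_n * y[t-1, n] + e[t, n]
# with uncorrelated random intercept u0_n and random slope u1_n and
# homogeneous innovation SD. The fixed slope beta1 estimates the
# population autocorrelation; beta1 plus the predicted random slope is
# the individual autocorrelation prediction, which is not constrained to
# the stationary region.
#
# The REML criterion is profiled analytically: with variance ratios
# theta = (sigma_u0/sigma_e, sigma_u1/sigma_e), each individual's marginal
# covariance is sigma_e^2 * W_n(theta) with W_n = I + theta0^2 11' +
# theta1^2 x x'. Woodbury reduces every quantity to 2x2 algebra in the
# per-individual Gram statistics, vectorized over individuals, so one
# criterion evaluation is O(N) scalar vector operations.

# Per-individual Gram statistics of the lag regression.
reml_prep <- function(scores) {
  T <- nrow(scores)
  x <- scores[-T, , drop = FALSE]
  y <- scores[-1, , drop = FALSE]
  list(m = T - 1L, N = ncol(scores),
       Sx = colSums(x), Sxx = colSums(x^2),
       Sy = colSums(y), Sxy = colSums(x * y), Syy = colSums(y^2))
}

# Profiled REML criterion and, on request, the full fitted quantities.
# theta = (sigma_u0/sigma_e, sigma_u1/sigma_e), both >= 0.
reml_eval <- function(theta, g, details = FALSE) {
  a2 <- theta[1]^2; b2 <- theta[2]^2
  m <- g$m
  M11 <- 1 + a2 * m
  M22 <- 1 + b2 * g$Sxx
  det2 <- M11 * M22 - a2 * b2 * g$Sx^2
  if (any(det2 <= 0) || any(!is.finite(det2))) return(Inf)
  K11 <- a2 * M22 / det2
  K12 <- -a2 * b2 * g$Sx / det2
  K22 <- b2 * M11 / det2
  # CK = C %*% K with C = [[m, Sx], [Sx, Sxx]]
  CK11 <- m * K11 + g$Sx * K12
  CK12 <- m * K12 + g$Sx * K22
  CK21 <- g$Sx * K11 + g$Sxx * K12
  CK22 <- g$Sx * K12 + g$Sxx * K22
  # A = U' W^-1 U = C - CK C ; v = U' W^-1 y = c - CK c ; w = y' W^-1 y
  A11 <- m - (CK11 * m + CK12 * g$Sx)
  A12 <- g$Sx - (CK11 * g$Sx + CK12 * g$Sxx)
  A22 <- g$Sxx - (CK21 * g$Sx + CK22 * g$Sxx)
  v1 <- g$Sy - (CK11 * g$Sy + CK12 * g$Sxy)
  v2 <- g$Sxy - (CK21 * g$Sy + CK22 * g$Sxy)
  w <- g$Syy - (K11 * g$Sy^2 + 2 * K12 * g$Sy * g$Sxy + K22 * g$Sxy^2)
  SA11 <- sum(A11); SA12 <- sum(A12); SA22 <- sum(A22)
  Sv1 <- sum(v1); Sv2 <- sum(v2)
  dA <- SA11 * SA22 - SA12^2
  if (dA <= 0 || !is.finite(dA)) return(Inf)
  beta1 <- (SA22 * Sv1 - SA12 * Sv2) / dA
  beta2 <- (SA11 * Sv2 - SA12 * Sv1) / dA
  r2 <- sum(w) - (beta1 * Sv1 + beta2 * Sv2)
  Mtot <- g$N * m
  if (r2 <= 0 || !is.finite(r2)) return(Inf)
  crit <- sum(log(det2)) + log(dA) + (Mtot - 2) * log(r2)
  if (!details) return(crit)
  sigma_e2 <- r2 / (Mtot - 2)
  # fixed-effect covariance sigma_e^2 (sum A)^-1
  cov_b <- sigma_e2 / dA * matrix(c(SA22, -SA12, -SA12, SA11), 2, 2)
  # BLUPs: u_hat_n = D_theta * (v_n - A_n beta)
  t1 <- v1 - A11 * beta1 - A12 * beta2
  t2 <- v2 - A12 * beta1 - A22 * beta2
  list(criterion = crit, beta = c(beta1, beta2), cov_beta = cov_b,
       sigma_e = sqrt(sigma_e2), u0 = a2 * t1, u1 = b2 * t2)
}

#' Profiled REML criterion of the random AR(1) model
#'
#' Returns the profiled restricted-likelihood criterion (-2 restricted
#' log-likelihood up to an additive constant, with the fixed effects and
#' the innovation SD concentrated out) as a function of the two variance
#' ratios `theta = c(sigma_u0 / sigma_e, sigma_u1 / sigma_e)`. Used by
#' [fit_mle_random()] and available directly so that the optimum can be
#' verified against a grid evaluation of the same surface.
#'
#' @param panel An `mlar1_panel` or a T x N score matrix.
#' @return A function of a length-2 non-negative numeric vector.
#' @export
reml_profile_criterion <- function(panel) {
  scores <- if (inherits(panel, "mlar1_panel")) panel$scores else as.matrix(panel)
  g <- reml_prep(scores)
  function(theta) reml_eval(theta, g)
}

#' Random-model (REML) estimator for a panel
#'
#' Fits, by restricted maximum likelihood, the linear mixed model with a
#' fixed intercept and fixed slope on the lagged score and uncorrelated
#' random intercepts and random slopes per individual. The fixed slope is
#' the population autocorrelation estimate; each individual's predicted
#' autocorrelation is the fixed slope plus the empirical best linear
#' unbiased prediction of that individual's random slope. Predictions are
#' not constrained to (-1, 1); `n_nonstationary` counts those with
#' absolute value above 1. Variance components may legally sit on the
#' zero boundary (flagged in `boundary`).
#'
#' @param panel An `mlar1_panel` or a T x N score matrix.
#' @param alpha Two-sided level of the t-based confidence interval
#'   (df = N - 2); default 0.05.
#' @param restarts Number of jittered optimizer restarts tried before the
#'   fit is declared non-converged; default 3.
#' @return An object of class `mlar1_random_fit`.
#' @export
fit_mle_random <- function(panel, alpha = 0.05, restarts = 3) {
  scores <- if (inherits(panel, "mlar1_panel")) panel$scores else as.matrix(panel)
  N <- ncol(scores)
  if (N < 2) stop("at least 2 individuals are needed")
  if (nrow(scores) < 3) stop("at least 3 time points are needed")
  g <- reml_prep(scores)
  obj <- function(th) reml_eval(th, g)
  starts <- list(c(0.5, 0.3))
  fit <- NULL; conv <- FALSE
  for (k in seq_len(restarts + 1L)) {
    st <- if (k == 1) starts[[1]] else abs(starts[[1]] + stats::runif(2, -0.3, 0.8))
    res <- tryCatch(
      stats::nlminb(st, obj, lower = c(0, 0),
                    control = list(rel.tol = 1e-12, x.tol = 1e-10,
                                   iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$objective)) {
      if (is.null(fit) || res$objective < fit$objective) fit <- res
      if (res$convergence == 0 ||
          grepl("singular convergence|relative convergence|X-convergence",
                res$message))
        conv <- TRUE
    }
    if (conv && k >= 1) break
  }
  if (is.null(fit)) {
    return(structure(
      list(gamma01_hat = NA_real_, se_gamma01 = NA_real_,
           gamma00_hat = NA_real_, sigma_u1_hat = NA_real_,
           sigma_u0_hat = NA_real_, sigma_e_hat = NA_real_,
           phi_individual = rep(NA_real_, N),
           ci_gamma01 = c(NA_real_, NA_real_),
           n_nonstationary = NA_integer_, converged = FALSE,
           boundary = NA, theta = c(NA_real_, NA_real_),
           criterion = NA_real_, alpha = alpha),
      class = "mlar1_random_fit"))
  }
  theta <- fit$par
  d <- reml_eval(theta, g, details = TRUE)
  se_g01 <- sqrt(d$cov_beta[2, 2])
  df <- N - 2L
  tq <- stats::qt(1 - alpha / 2, df)
  phi_ind <- d$beta[2] + d$u1
  # implied population mean: intercept / (1 - slope)
  g00 <- if (abs(1 - d$beta[2]) > 1e-8) d$beta[1] / (1 - d$beta[2]) else NA_real_
  structure(
    list(gamma01_hat = d$beta[2], se_gamma01 = se_g01,
         gamma00_hat = g00,
         sigma_u1_hat = theta[2] * d$sigma_e,
         sigma_u0_hat = theta[1] * d$sigma_e,
         sigma_e_hat = d$sigma_e,
         phi_individual = phi_ind,
         u0_individual = d$u0,
         ci_gamma01 = c(d$beta[2] - tq * se_g01, d$beta[2] + tq * se_g01),
         n_nonstationary = as.integer(sum(abs(phi_ind) > 1)),
         converged = conv, boundary = any(theta < 1e-6),
         theta = theta, criterion = d$criterion,
         fixef = d$beta, alpha = alpha),
    class = "mlar1_random_fit")
}

#' @export
print.mlar1_random_fit <- function(x, ...) {
  cat("Random-model REML fit (random intercept + random slope on lag)\n")
  cat(sprintf("  gamma01_hat = %.4f (SE %.4f), %d%% CI [%.4f, %.4f]\n",
              x$gamma01_hat, x$se_gamma01, round(100 * (1 - x$alpha)),
              x$ci_gamma01[1], x$ci_gamma01[2]))
  cat(sprintf("  sigma_u0 = %.4f, sigma_u1 = %.4f, sigma_e = %.4f%s\n",
              x$sigma_u0_hat, x$sigma_u1_hat, x$sigma_e_hat,
              if (isTRUE(x$boundary)) " (boundary)" else ""))
  cat(sprintf("  %d individual prediction(s) outside the stationary region\n",
              x$n_nonstationary))
  invisible(x)
}
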