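# Single-series exact AR(1) maximum likelihood: checked against a
# brute-force grid maximization of the directly computed likelihood, the
# time-reversal symmetry of the stationary Gaussian model, and
# large-sample consistency.

# Independent grid-search oracle: evaluates the deviance from raw
# residuals (no profiling shortcuts) on nested refined lattices.
grid_mle_oracle <- function(y) {
  Tn <- length(y)
  dev <- function(mu, phi, sg) {
    ss <- (1 - phi^2) * (y[1] - mu)^2 +
      sum((y[-1] - mu - phi * (y[-Tn] - mu))^2)
    Tn * log(sg^2) - log(1 - phi^2) + ss / sg^2
  }
  search <- function(mus, phis, sgs) {
    best <- Inf; arg <- NULL
    for (phi in phis) for (mu in mus) for (sg in sgs) {
      v <- dev(mu, phi, sg)
      if (v < best) { best <- v; arg <- c(mu, phi, sg) }
    }
    arg
  }
  mus <- seq(mean(y) - 3 * sd(y), mean(y) + 3 * sd(y), length.out = 80)
  phis <- seq(-0.999, 0.999, length.out = 81)
  sgs <- exp(seq(log(sd(y) / 5), log(sd(y) * 3), length.out = 80))
  arg <- search(mus, phis, sgs)
  for (shrink in c(10, 100, 1000)) {
    mus <- seq(arg[1] - 6 * sd(y) / shrink, arg[1] + 6 * sd(y) / shrink,
               length.out = 41)
    phis <- pmax(-0.9999, pmin(0.9999,
      seq(arg[2] - 2 / shrink, arg[2] + 2 / shrink, length.out = 41)))
    sgs <- seq(arg[3] * (1 - 2 / shrink), arg[3] * (1 + 2 / shrink),
               length.out = 41)
    arg <- search(mus, phis, sgs)
  }
  arg
}

test_that("ML fit matches the grid-search likelihood oracle", {
  for (seed in c(21, 22)) {
    y <- generate_series(0.5, c(0.4, -0.5)[seed - 20], 1, 10, seed = seed)
    orc <- grid_mle_oracle(y)
    fit <- fit_ar1_single(y)
    expect_lt(abs(fit$mu_hat - orc[1]), 1e-3)
    expect_lt(abs(fit$phi_hat - orc[2]), 1e-3)
    expect_lt(abs(fit$sigma_e_hat - orc[3]), 1e-3)
    # the reported optimum is at least as good as the oracle's
    expect_lte(ar1_negloglik(y, fit$mu_hat, fit$phi_hat, fit$sigma_e_hat),
               ar1_negloglik(y, orc[1], orc[2], orc[3]) + 1e-8)
  }
})

test_that("stationary likelihood is invariant under time reversal", {
  cases <- data.frame(seed = 31:34, phi = c(0.4, -0.6, 0.1, 0.8))
  for (i in seq_len(nrow(cases))) {
    y <- generate_series(1, cases$phi[i], 1, 20, seed = cases$seed[i])
    f1 <- fit_ar1_single(y)
    f2 <- fit_ar1_single(rev(y))
    expect_lt(abs(f1$phi_hat - f2$phi_hat), 1e-6)
  }
})

test_that("estimates are consistent at large T and stay stationary", {
  y <- generate_series(0, 0.6, 1, 1e5, seed = 41)
  fit <- fit_ar1_single(y)
  expect_lt(abs(fit$phi_hat - 0.6), 0.01)
  expect_true(fit$converged)
  expect_lt(abs(fit$phi_hat), 1)
  expect_true(fit$interval_phi[1] <= fit$phi_hat &&
                fit$phi_hat <= fit$interval_phi[2])
})

test_that("degenerate input is rejected", {
  expect_error(fit_ar1_single(rep(1, 10)), "degenerate series")
  expect_error(fit_ar1_single(c(1, 2)), "at least 3")
})
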