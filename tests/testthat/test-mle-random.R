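# Random-model REML estimator: cross-checked against lme4 (the
# established mixed-model routine fitting the same specification), the
# profiled-criterion grid, and parameter-recovery properties.

test_that("REML fit agrees with lme4 on seeded panels", {
  skip_if_not_installed("lme4")
  worst <- 0
  for (i in 1:20) {
    pars <- list(T = c(10, 25)[i %% 2 + 1], N = c(10, 25)[(i %/% 2) %% 2 + 1],
                 g = seq(-0.6, 0.6, length.out = 20)[i],
                 s = seq(0.2, 0.4, length.out = 20)[i])
    cond <- mlar1_condition(T = pars$T, N = pars$N, gamma01 = pars$g,
                            sigma_u1 = pars$s)
    p <- generate_panel(cond, seed = 5000 + i)
    fr <- fit_mle_random(p)
    Tn <- nrow(p$scores)
    df <- data.frame(y = as.vector(p$scores[-1, ]),
                     x = as.vector(p$scores[-Tn, ]),
                     id = rep(seq_len(ncol(p$scores)), each = Tn - 1))
    lf <- suppressWarnings(suppressMessages(
      lme4::lmer(y ~ x + (1 | id) + (0 + x | id), data = df, REML = TRUE)))
    worst <- max(worst, abs(lme4::fixef(lf)[["x"]] - fr$gamma01_hat))
    expect_lt(abs(lme4::fixef(lf)[["x"]] - fr$gamma01_hat), 1e-4)
    expect_lt(abs(sqrt(vcov(lf)[2, 2]) - fr$se_gamma01), 1e-4)
    blup <- lme4::fixef(lf)[["x"]] + lme4::ranef(lf)$id[, "x"]
    expect_lt(max(abs(blup - fr$phi_individual)), 1e-4)
  }
})

test_that("REML optimum dominates a grid over the profiled surface", {
  p <- generate_panel(mlar1_condition(T = 6, N = 4, gamma01 = 0.3,
                                      sigma_u1 = 0.4), seed = 77)
  crit <- reml_profile_criterion(p)
  fit <- fit_mle_random(p)
  grid_vals <- outer(seq(0, 3, length.out = 50),
                     seq(0, 3, length.out = 50),
                     Vectorize(function(a, b) crit(c(a, b))))
  expect_lte(fit$criterion, min(grid_vals) + 1e-6)
})

test_that("degenerate hierarchy is recovered with a near-zero slope SD", {
  cond <- mlar1_condition(T = 1e4, N = 25, gamma01 = 0.4, sigma_u1 = 1e-12,
                          sigma_u0 = 0)
  p <- generate_panel(cond, seed = 88)
  fit <- fit_mle_random(p)
  expect_lt(fit$sigma_u1_hat, 0.01)
  expect_lt(abs(fit$gamma01_hat - 0.4), 0.02)
})

test_that("population autocorrelation is recovered with small bias at
           large N and T", {
  cond <- mlar1_condition(T = 100, N = 100, gamma01 = 0.3, sigma_u1 = 0.25)
  est <- vapply(seq_len(200), function(r) {
    p <- generate_panel(cond, seed = replication_seed(31, cond, r))
    fit_mle_random(p)$gamma01_hat
  }, 0)
  # compare against the truncated-normal mean actually generated
  z <- integrate(function(x) dnorm(x, 0.3, 0.25), -1, 1)$value
  m_true <- integrate(function(x) x * dnorm(x, 0.3, 0.25) / z, -1, 1)$value
  expect_lt(abs(mean(est) - m_true), 0.02)
})

test_that("confidence interval uses the two-sided t quantile with N - 2 df", {
  p <- generate_panel(mlar1_condition(T = 10, N = 10, gamma01 = 0,
                                      sigma_u1 = 0.25), seed = 9)
  for (fit in list(fit_mle_random(p), fit_mle_fixed(p))) {
    mult <- (fit$ci_gamma01[2] - fit$gamma01_hat) / fit$se_gamma01
    expect_equal(mult, qt(0.975, 8), tolerance = 1e-10)
  }
})

test_that("biases at +gamma and -gamma mirror each other", {
  biases <- sapply(c(-0.3, 0.3), function(g) {
    cond <- mlar1_condition(T = 10, N = 10, gamma01 = g, sigma_u1 = 0.40)
    r <- run_condition(cond, "MLE-R", R = 500, master_seed = 51)
    c(r$summary$bias_gamma01, r$summary$empirical_sd)
  })
  se_sum <- sqrt(sum(biases[2, ]^2 / 500))
  expect_lt(abs(biases[1, 1] + biases[1, 2]), 3 * se_sum + 0.01)
})
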