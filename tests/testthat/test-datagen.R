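# Generator checks: the truncated-normal autocorrelation sampler against
# an independent rejection-sampling oracle, stationarity of the series,
# and full reproducibility under seeding.

test_that("truncated-normal sampler matches a rejection-sampling oracle", {
  n <- 1e5
  draws <- sample_phi(0.6, 0.4, n, seed = 101)
  expect_true(all(abs(draws) < 1))
  # oracle: plain normal draws, discard those outside (-1, 1)
  set.seed(202)
  raw <- rnorm(3e5, 0.6, 0.4)
  orc <- raw[abs(raw) < 1][seq_len(n)]
  se_mean <- sd(orc) / sqrt(n)
  expect_lt(abs(mean(draws) - mean(orc)), 3 * sqrt(2) * se_mean)
  se_sd <- sd(orc) / sqrt(2 * n)
  expect_lt(abs(sd(draws) - sd(orc)), 3 * sqrt(2) * se_sd)
  for (p in c(0.01, 0.99)) {
    q_o <- quantile(orc, p, names = FALSE)
    # asymptotic quantile SE from the truncated-normal density
    dens <- dnorm(q_o, 0.6, 0.4) /
      (pnorm(1, 0.6, 0.4) - pnorm(-1, 0.6, 0.4))
    se_q <- sqrt(p * (1 - p) / n) / dens
    expect_lt(abs(quantile(draws, p, names = FALSE) - q_o),
              3 * sqrt(2) * se_q)
  }
})

test_that("truncated sampler limits: vanishing variance and symmetry", {
  d <- sample_phi(0.6, 1e-12, 5, seed = 1)
  expect_true(all(abs(d - 0.6) < 1e-6))
  d0 <- sample_phi(0, 0.40, 1e5, seed = 2)
  expect_lt(abs(mean(d0)), 3 * sd(d0) / sqrt(1e5))
  skw <- mean((d0 - mean(d0))^3) / sd(d0)^3
  expect_lt(abs(skw), 0.03)
  expect_error(sample_phi(1.2, 0.4, 5), "gamma01")
  expect_error(sample_phi(0, -1, 5), "sigma_u1")
})

test_that("generated series have the stationary AR(1) moments", {
  y <- generate_series(0, 0, 1, 1e5, seed = 3)
  r1 <- cor(y[-1], y[-length(y)])
  expect_lt(abs(r1), 3 / sqrt(1e5))
  y <- generate_series(0, 0.6, 1, 1e5, seed = 4)
  expect_lt(abs(var(y) - 1 / (1 - 0.36)), 5 * 1.5625 * sqrt(2 / 1e5) /
              sqrt(1 - 0.36))
  y <- generate_series(5, -0.6, 1, 1e5, seed = 5)
  expect_lt(abs(mean(y) - 5), 0.05)
  acov <- mean((y[-1] - mean(y)) * (y[-length(y)] - mean(y)))
  expect_lt(abs(acov / var(y) - (-0.6)), 0.02)
  expect_error(generate_series(0, 1.1, 1, 10), "stationarity")
  expect_error(generate_series(0, 0.5, -1, 10), "sigma_e")
})

test_that("standardized innovations have exact realized moments", {
  y <- generate_series(0, 0.5, 1, 50, seed = 6,
                       standardize_innovations = TRUE)
  e <- y[-1] - 0.5 * y[-50]  # mu = 0, so innovations recoverable exactly
  expect_equal(mean(e), 0, tolerance = 1e-12)
  expect_equal(sd(e), 1, tolerance = 1e-12)
})

test_that("panels are reproducible and degenerate hierarchies collapse", {
  cond <- mlar1_condition(T = 10, N = 10, gamma01 = 0, sigma_u1 = 0.40)
  p1 <- generate_panel(cond, seed = 7)
  p2 <- generate_panel(cond, seed = 7)
  expect_identical(p1$scores, p2$scores)
  expect_identical(p1$phi_true, p2$phi_true)
  expect_true(all(abs(p1$phi_true) < 1))
  expect_equal(dim(p1$scores), c(10L, 10L))
  expect_false(anyNA(p1$scores))
  cond0 <- mlar1_condition(T = 10, N = 5, gamma01 = 0.3, sigma_u1 = 1e-12,
                           sigma_u0 = 0)
  p0 <- generate_panel(cond0, seed = 8)
  expect_true(all(abs(p0$phi_true - 0.3) < 1e-6))
  expect_true(all(p0$mu_true == 0))
})

test_that("panel-mean autocorrelation matches the quadrature oracle", {
  cond <- mlar1_condition(T = 25, N = 25, gamma01 = 0.3, sigma_u1 = 0.25)
  means <- vapply(seq_len(2000), function(r) {
    mean(generate_panel(cond, seed = replication_seed(11, cond, r))$phi_true)
  }, 0)
  # truncated-normal mean by numeric integration
  z <- integrate(function(x) dnorm(x, 0.3, 0.25), -1, 1)$value
  m_true <- integrate(function(x) x * dnorm(x, 0.3, 0.25) / z, -1, 1)$value
  expect_lt(abs(mean(means) - m_true), 3 * sd(means) / sqrt(2000))
})
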