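# Bayesian estimators: reference-prior closed forms, distributional
# correctness of the samplers (conjugate reduction against quadrature,
# prior recovery under a flattened likelihood, likelihood domination),
# and the hierarchical model's behaviour on seeded panels.

test_that("reference prior has its closed form, symmetry and unit mass", {
  expect_equal(log_reference_prior_phi(0), log(1 / pi), tolerance = 1e-12)
  expect_equal(log_reference_prior_phi(0.9), log_reference_prior_phi(-0.9))
  expect_identical(log_reference_prior_phi(1.5), -Inf)
  mass <- integrate(function(x) exp(log_reference_prior_phi(x)), -1, 1,
                    rel.tol = 1e-12)$value
  expect_equal(mass, 1, tolerance = 1e-8)
})

test_that("sampler matches quadrature on the conjugate reduction (phi = 0)", {
  set.seed(5)
  y <- rnorm(50, 1.2, 0.8)
  fit <- fit_bayes_fixed(matrix(y),
                         settings = mcmc_settings(iterations = 8000,
                                                  burn_in = 2000),
                         seed = 11, fix_phi = 0)
  per <- fit$per_individual
  mus <- seq(0.5, 2, length.out = 400)
  sgs <- seq(0.4, 1.6, length.out = 400)
  lp <- outer(mus, sgs, function(m, s) {
    vapply(seq_along(m), function(i)
      sum(dnorm(y, m[i], s[i], log = TRUE)), 0) +
      dnorm(m, 0, 2, log = TRUE) + dgamma(s, 2, 2, log = TRUE)
  })
  w <- exp(lp - max(lp)); w <- w / sum(w)
  mu_qd <- sum(rowSums(w) * mus)
  sg_qd <- sum(colSums(w) * sgs)
  # 3 x (batch-means flavored) Monte-Carlo allowance on 24k correlated draws
  expect_lt(abs(per$mean[per$parameter == "mu"] - mu_qd), 0.02)
  expect_lt(abs(per$mean[per$parameter == "sigma_e"] - sg_qd), 0.02)
})

test_that("flattened likelihood returns the reference prior for phi", {
  # conditional likelihood with sigma_e pinned very large: the posterior
  # of phi reduces to the prior; compare interval masses with the
  # arcsine closed form
  ch <- mlar1sim:::.bayf_sampler_cpp(c(0.01, -0.02, 0.015), 4, 12000, 2000,
                                     0, 2, 2, 2, TRUE, NA_real_, 1000)
  phid <- unlist(lapply(ch, function(m) m[, 2]))
  prior_mass <- function(a, b) (asin(b) - asin(a)) / pi
  for (iv in list(c(-0.05, 0.05), c(0.85, 0.95), c(-0.95, -0.85))) {
    emp <- mean(phid > iv[1] & phid < iv[2])
    tru <- prior_mass(iv[1], iv[2])
    se <- sqrt(tru * (1 - tru) / (length(phid) / 10))  # ESS-deflated
    expect_lt(abs(emp - tru), 3 * se)
  }
})

test_that("posterior concentrates on the truth when data dominate", {
  y <- generate_series(0, 0.6, 1, 1e4, seed = 2)
  fit <- fit_bayes_fixed(matrix(y), seed = 3)
  expect_lt(abs(fit$gamma01_hat - 0.6), 0.02)
  expect_error(fit_bayes_fixed(matrix(rep(1, 10))), "degenerate series")
})

test_that("hierarchical model recovers the population autocorrelation on
           a seeded panel and keeps SD support positive", {
  p <- generate_panel(mlar1_condition(T = 25, N = 25, gamma01 = 0.3,
                                      sigma_u1 = 0.25), seed = 42)
  fit <- fit_bayes_random(p, seed = 7)
  expect_lt(abs(fit$gamma01_hat - 0.3), 0.15)
  su1 <- fit$summary[fit$summary$parameter == "sigma_u1", ]
  expect_gt(su1$cri_lower, 0)
  # individual predictions are stationary by construction
  expect_true(all(abs(fit$phi_individual) < 1))
  expect_identical(fit$n_nonstationary, 0L)
})

test_that("hierarchical credible intervals keep the actual alpha near
           its nominal level", {
  # scaled-down: 100 replications bound the rejection rate loosely but
  # honestly (binomial 95% band around 0.05 is about +/- 0.045)
  cond <- mlar1_condition(T = 10, N = 10, gamma01 = 0, sigma_u1 = 0.25)
  r <- run_condition(cond, "BAY-R", R = 100, master_seed = STUDY_SEED)
  expect_lte(r$summary$epr, 0.12)
})

test_that("prior choice moves the posterior means only a little in the
           sensitivity experiment", {
  # common random numbers across the nine prior settings isolate the
  # prior effect; at reduced replications the spreads should stay on the
  # order of the bands seen at full scale (a few hundredths)
  sens <- run_prior_sensitivity(R = 30, master_seed = STUDY_SEED)
  g_r <- sens$mean_gamma01_hat[sens$estimator == "BAY-R"]
  g_f <- sens$mean_gamma01_hat[sens$estimator == "BAY-F"]
  expect_length(g_r, 9)
  expect_length(g_f, 7)
  expect_lt(diff(range(g_r)), 0.06)
  expect_lt(diff(range(g_f)), 0.10)
  # the fixed-model location estimate reacts to its location prior
  mu_f <- sens$mean_mu_hat[sens$estimator == "BAY-F"]
  expect_lt(diff(range(mu_f)), 0.3)
})
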