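# Outcome measures on hand-constructed replication records.

mk_records <- function(gamma01_hat, se = 0.1, sigma_u1 = 0.25,
                       lo = NULL, hi = NULL) {
  R <- length(gamma01_hat)
  if (is.null(lo)) lo <- gamma01_hat - 2 * se
  if (is.null(hi)) hi <- gamma01_hat + 2 * se
  data.frame(estimator = "MLE-R", r = seq_len(R),
             gamma01_hat = gamma01_hat, se_gamma01 = se,
             sigma_u1_hat = sigma_u1, ci_lower = lo, ci_upper = hi,
             rejected_h0 = lo > 0 | hi < 0, n_nonconverged = 0L,
             n_nonstationary = 0L, n_individuals = 10L, converged = TRUE)
}

test_that("bias, empirical SD and SE bias are plain arithmetic", {
  rec <- mk_records(c(0.1, 0.3))
  expect_equal(bias_gamma01(rec, 0.3), -0.1)
  expect_equal(bias_gamma01(mk_records(rep(0.25, 5)), 0.25), 0)
  expect_equal(empirical_sd(mk_records(c(0, 0.2))), sd(c(0, 0.2)))
  expect_equal(empirical_sd(mk_records(rep(0.4, 8))), 0)
  rec <- mk_records(c(0.1, 0.1 + sqrt(2) * 0.15), se = 0.2)
  expect_equal(bias_se(rec), 0.2 - sd(rec$gamma01_hat))
  rec2 <- mk_records(c(0, 0.2), se = sd(c(0, 0.2)))
  expect_equal(bias_se(rec2), 0)
  expect_error(bias_gamma01(rec[0, ], 0), "no replication records")
})

test_that("between-person SD path for fixed estimators is the sample SD", {
  phi <- c(0.0, 0.2, 0.4)
  expect_equal(sd(phi), 0.2)  # the aggregation rule uses the n-1 SD
  scores <- sapply(1:5, function(i) generate_series(0, 0.3, 1, 12,
                                                    seed = 70))
  fit <- fit_mle_fixed(scores)
  expect_equal(fit$sigma_u1_hat, 0)  # identical series, zero dispersion
  expect_equal(bias_sigma_u1(mk_records(0.1, sigma_u1 = 0.3), 0.25),
               0.05)
})

test_that("rejection rate counts intervals excluding zero", {
  rec <- mk_records(c(0.3, 0.05), lo = c(0.1, -0.2), hi = c(0.5, 0.3))
  expect_equal(epr(rec), 0.5)
  rec <- mk_records(c(0, 0), lo = c(-1, -1), hi = c(1, 1))
  expect_equal(epr(rec), 0)
})

test_that("percentile interval follows the linear-interpolation rule", {
  rec <- mk_records(seq(0, 1, length.out = 41))
  ie <- interval_estimate(rec)
  expect_equal(unname(ie), c(0.025, 0.975))
  # brute-force oracle for the type-7 definition at arbitrary p
  x <- sort(rec$gamma01_hat)
  p <- 0.025; h <- (length(x) - 1) * p
  orc <- x[floor(h) + 1] + (h - floor(h)) * (x[floor(h) + 2] - x[floor(h) + 1])
  expect_equal(unname(ie["lower"]), orc)
})

test_that("summaries are invariant to replication order and count
           problems per individual prediction", {
  set.seed(71)
  rec <- mk_records(rnorm(50, 0.2, 0.1))
  rec$n_nonstationary[c(3, 9)] <- c(2L, 1L)
  cond <- mlar1_condition(T = 10, N = 10, gamma01 = 0.2, sigma_u1 = 0.25)
  s1 <- summarize_condition(rec, cond)
  s2 <- summarize_condition(rec[sample(nrow(rec)), ], cond)
  for (col in c("bias_gamma01", "empirical_sd", "bias_se", "epr",
                "interval_lower", "interval_upper", "pct_nonstationary"))
    expect_equal(s1[[col]], s2[[col]])
  expect_equal(s1$pct_nonstationary, 100 * 3 / 500)
  rec0 <- mk_records(rnorm(10, 0.2, 0.1))
  expect_equal(summarize_condition(rec0, cond)$pct_nonstationary, 0)
})
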