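# Study runner: determinism, prefix/condition independence, resumable
# output, configuration round trips.

test_that("runs are deterministic and shorter runs are exact prefixes", {
  cond <- mlar1_condition(T = 10, N = 10, gamma01 = 0, sigma_u1 = 0.40)
  a <- run_condition(cond, "MLE-R", R = 3, master_seed = 123)
  b <- run_condition(cond, "MLE-R", R = 3, master_seed = 123)
  expect_identical(a$records, b$records)
  long <- run_condition(cond, "MLE-R", R = 6, master_seed = 123)
  expect_identical(a$records, long$records[1:3, ])
  # a different master seed gives different replications
  c <- run_condition(cond, "MLE-R", R = 3, master_seed = 124)
  expect_false(identical(a$records$gamma01_hat, c$records$gamma01_hat))
})

test_that("replication seeds stay in 31 bits and separate streams", {
  cond <- mlar1_condition(T = 10, N = 10, gamma01 = 0.3, sigma_u1 = 0.25)
  s <- vapply(1:500, function(r) replication_seed(1, cond, r), 0L)
  expect_true(all(s >= 1 & s <= 2^31 - 2))
  expect_equal(length(unique(s)), 500)
  expect_false(replication_seed(1, cond, 1, stream = 0) ==
                 replication_seed(1, cond, 1, stream = 1))
  cond2 <- mlar1_condition(T = 25, N = 10, gamma01 = 0.3, sigma_u1 = 0.25)
  expect_false(replication_seed(1, cond, 1) == replication_seed(1, cond2, 1))
})

test_that("run_study writes resumable per-cell files and reloads them", {
  out <- file.path(tempdir(), "mlar1sim-study-test")
  unlink(out, recursive = TRUE)
  cfg <- study_config(T_values = 10, N_values = 10,
                      sigma_u1_values = 0.25, gamma01_values = c(0, 0.3),
                      replications = 5, estimators = c("MLE-F", "MLE-R"),
                      master_seed = 9, out_dir = out)
  s1 <- run_study(cfg)
  expect_equal(nrow(s1), 4)
  expect_true(file.exists(file.path(out, "summaries.csv")))
  # second run must reload the cells from disk, bit-identically
  s2 <- run_study(cfg)
  expect_equal(s2$bias_gamma01, s1$bias_gamma01, tolerance = 0)
  expect_equal(s2$interval_upper, s1$interval_upper, tolerance = 0)
  unlink(out, recursive = TRUE)
})

test_that("an empty estimator list yields an empty result", {
  cfg <- study_config(T_values = 10, N_values = 10,
                      sigma_u1_values = 0.25, gamma01_values = 0,
                      replications = 2, estimators = character(0))
  expect_equal(nrow(run_study(cfg)), 0)
})

test_that("the default configuration spans the full crossed design", {
  cfg <- study_config()
  conds <- condition_grid(cfg)
  expect_length(conds, 40)
  expect_equal(cfg$replications, 2000L)
  expect_equal(study_config(replications = "smoke")$replications, 50L)
  expect_error(study_config(estimators = "GLS"), "unknown estimator")
})

test_that("configurations round-trip through YAML and JSON", {
  cfg_list <- list(T_values = c(10, 25), N_values = 10,
                   sigma_u1_values = 0.4, gamma01_values = c(-0.3, 0.3),
                   replications = 7, estimators = c("MLE-R"),
                   alpha = 0.1, master_seed = 77,
                   mcmc = list(chains = 2, iterations = 400,
                               burn_in = 100))
  jf <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg_list, jf, auto_unbox = TRUE)
  cfg <- read_study_config(jf)
  expect_equal(cfg$replications, 7L)
  expect_equal(cfg$alpha, 0.1)
  expect_equal(cfg$mcmc$chains, 2L)
  expect_length(condition_grid(cfg), 4)
  skip_if_not_installed("yaml")
  yf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg_list, yf)
  cfg2 <- read_study_config(yf)
  expect_equal(cfg2$master_seed, 77L)
  expect_equal(cfg2$mcmc$iterations, 400L)
})

test_that("rejection rate is monotone in the autocorrelation magnitude", {
  eprs <- sapply(list(c("MLE-F", 300), c("MLE-R", 300), c("BAY-F", 40),
                      c("BAY-R", 40)), function(es) {
    sapply(c(0, 0.3, 0.6), function(g) {
      cond <- mlar1_condition(T = 25, N = 25, gamma01 = g, sigma_u1 = 0.25)
      run_condition(cond, es[1], R = as.integer(es[2]),
                    master_seed = STUDY_SEED,
                    mcmc = mcmc_settings())$summary$epr
    })
  })
  colnames(eprs) <- c("MLE-F", "MLE-R", "BAY-F", "BAY-R")
  for (est in colnames(eprs)) {
    R <- if (grepl("MLE", est)) 300 else 40
    mc <- 2 * sqrt(0.25 / R)  # worst-case binomial SE, twice
    expect_true(all(diff(eprs[, est]) > -mc),
                info = paste(est, paste(round(eprs[, est], 3),
                                        collapse = " ")))
  }
})
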