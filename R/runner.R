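# Study runner: the fully crossed simulation design (default 40
# conditions), deterministic per-replication seeding, and the
# prior-sensitivity harness.

ESTIMATORS <- c("MLE-F", "MLE-R", "BAY-F", "BAY-R")

#' Study configuration
#'
#' Bundles the design grid, replication count, estimators, priors, MCMC
#' settings and seeding for a full study run. The default grid is the
#' fully crossed design: `T` and `N` in `{10, 25}`, between-person SD in
#' `{0.25, 0.40}`, and population autocorrelation in
#' `{-0.6, -0.3, 0, 0.3, 0.6}` - 40 conditions.
#'
#' @param T_values,N_values,sigma_u1_values,gamma01_values Grid levels.
#' @param replications Replications per condition; default 2000
#'   (preset `"full"`); `"smoke"` uses 50.
#' @param estimators Character subset of
#'   `c("MLE-F", "MLE-R", "BAY-F", "BAY-R")`.
#' @param priors A [prior_spec()].
#' @param mcmc An [mcmc_settings()].
#' @param alpha Test level; default 0.05.
#' @param master_seed Master seed; every replication seed is derived from
#'   it, the condition parameters and the replication index.
#' @param out_dir Optional output directory for [run_study()].
#' @return An object of class `mlar1_study_config`.
#' @export
study_config <- function(T_values = c(10, 25), N_values = c(10, 25),
                         sigma_u1_values = c(0.25, 0.40),
                         gamma01_values = c(-0.6, -0.3, 0, 0.3, 0.6),
                         replications = 2000,
                         estimators = ESTIMATORS,
                         priors = prior_spec(), mcmc = mcmc_settings(),
                         alpha = 0.05, master_seed = 1L,
                         out_dir = NULL) {
  if (is.character(replications))
    replications <- switch(replications, full = 2000L, smoke = 50L,
                           stop("unknown replication preset"))
  bad <- setdiff(estimators, ESTIMATORS)
  if (length(bad)) stop("unknown estimator(s): ", paste(bad, collapse = ", "))
  structure(
    list(T_values = T_values, N_values = N_values,
         sigma_u1_values = sigma_u1_values,
         gamma01_values = gamma01_values,
         replications = as.integer(replications),
         estimators = estimators, priors = priors, mcmc = mcmc,
         alpha = alpha, master_seed = as.integer(master_seed),
         out_dir = out_dir),
    class = "mlar1_study_config")
}

#' Enumerate the conditions of a study configuration
#'
#' @param config A [study_config()].
#' @return A list of [mlar1_condition()] objects in canonical order
#'   (gamma01 varying fastest, then sigma_u1, N, T).
#' @export
condition_grid <- function(config) {
  grid <- expand.grid(gamma01 = config$gamma01_values,
                      sigma_u1 = config$sigma_u1_values,
                      N = config$N_values, T = config$T_values,
                      KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    mlar1_condition(T = grid$T[i], N = grid$N[i],
                    gamma01 = grid$gamma01[i],
                    sigma_u1 = grid$sigma_u1[i]))
}

#' Derive the seed of one replication
#'
#' Mixes the master seed, the condition parameters and the replication
#' index into a 31-bit integer, so every replication has its own
#' reproducible RNG stream and adding conditions or replications never
#' perturbs existing ones.
#'
#' @param master_seed Integer master seed.
#' @param condition An [mlar1_condition()].
#' @param r Replication index.
#' @param stream Extra stream index (0 for panel generation; estimators
#'   that need their own randomness use a different stream).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
replication_seed <- function(master_seed, condition, r, stream = 0) {
  M <- 2147483647
  h <- as.numeric(master_seed) %% M
  vals <- c(condition$T, condition$N,
            round(1000 * condition$gamma01),
            round(1000 * condition$sigma_u1),
            round(1000 * condition$gamma00),
            round(1000 * condition$sigma_u0),
            round(1000 * condition$sigma_e),
            r, stream)
  for (v in vals) h <- (h * 69069 + v + 10007) %% M
  as.integer(h %% (M - 1) + 1)
}

fit_one <- function(panel, estimator, alpha, priors, mcmc, mcmc_seed) {
  switch(estimator,
    "MLE-F" = fit_mle_fixed(panel, alpha = alpha),
    "MLE-R" = fit_mle_random(panel, alpha = alpha),
    "BAY-F" = fit_bayes_fixed(panel, priors = priors, settings = mcmc,
                              alpha = alpha, seed = mcmc_seed),
    "BAY-R" = fit_bayes_random(panel, priors = priors, settings = mcmc,
                               alpha = alpha, seed = mcmc_seed),
    stop("unknown estimator: ", estimator))
}

#' Run one condition for one estimator
#'
#' For each replication r = 1..R: derive the replication seed, generate a
#' panel, fit the estimator, and record the estimates. Fit failures are
#' caught, logged and counted - they never abort the condition. The
#' result is deterministic given `(condition, estimator, R, master_seed)`
#' and identical to the corresponding rows of a longer run, because each
#' replication has its own derived seed.
#'
#' @param condition An [mlar1_condition()].
#' @param estimator One of `"MLE-F"`, `"MLE-R"`, `"BAY-F"`, `"BAY-R"`.
#' @param R Number of replications.
#' @param master_seed Integer master seed.
#' @param alpha Test level; default 0.05.
#' @param priors,mcmc Settings for the Bayesian estimators.
#' @param standardize_innovations Passed to [generate_panel()].
#' @param progress Print a progress line every `progress` replications
#'   (0 = silent).
#' @return List with `records` (data frame, one row per replication) and
#'   `summary` (from [summarize_condition()]).
#' @export
run_condition <- function(condition, estimator, R, master_seed,
                          alpha = 0.05, priors = prior_spec(),
                          mcmc = mcmc_settings(),
                          standardize_innovations = FALSE,
                          progress = 0) {
  if (!estimator %in% ESTIMATORS)
    stop("unknown estimator: ", estimator)
  R <- as.integer(R)
  g01 <- se <- su1 <- lo <- hi <- rep(NA_real_, R)
  rej <- conv <- rep(FALSE, R)
  nnc <- nns <- rep(0L, R)
  nind <- rep(condition$N, R)
  t0 <- proc.time()[["elapsed"]]
  for (r in seq_len(R)) {
    seed <- replication_seed(master_seed, condition, r, stream = 0)
    panel <- generate_panel(condition, seed = seed,
                            standardize_innovations = standardize_innovations)
    mseed <- replication_seed(master_seed, condition, r, stream = 1)
    fit <- tryCatch(
      fit_one(panel, estimator, alpha, priors, mcmc, mseed),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(fit$converged) || isTRUE(fit$converged) ||
         estimator == "MLE-F")) {
      g01[r] <- fit$gamma01_hat
      se[r] <- fit$se_gamma01
      su1[r] <- fit$sigma_u1_hat
      lo[r] <- fit$ci_gamma01[1]; hi[r] <- fit$ci_gamma01[2]
      rej[r] <- if (!is.null(fit$rejected_h0)) fit$rejected_h0
                else !is.na(lo[r]) && (lo[r] > 0 || hi[r] < 0)
      if (!is.null(fit$n_nonconverged)) nnc[r] <- fit$n_nonconverged
      if (!is.null(fit$n_nonstationary)) nns[r] <- fit$n_nonstationary
      conv[r] <- TRUE
    }
    if (progress > 0 && r %% progress == 0)
      message(sprintf("  [%s] T=%d N=%d g01=%+.2f su1=%.2f  rep %d/%d (%.1fs)",
                      estimator, condition$T, condition$N,
                      condition$gamma01, condition$sigma_u1, r, R,
                      proc.time()[["elapsed"]] - t0))
  }
  records <- data.frame(
    estimator = estimator, r = seq_len(R), gamma01_hat = g01,
    se_gamma01 = se, sigma_u1_hat = su1, ci_lower = lo, ci_upper = hi,
    rejected_h0 = rej, n_nonconverged = nnc, n_nonstationary = nns,
    n_individuals = nind, converged = conv)
  list(records = records,
       summary = summarize_condition(records, condition))
}

cell_key <- function(condition, estimator) {
  sprintf("%s_T%d_N%d_g%+0.2f_s%.2f", estimator, condition$T,
          condition$N, condition$gamma01, condition$sigma_u1)
}

#' Run the full study
#'
#' Iterates every condition x estimator cell of the configuration,
#' writing one tidy summary CSV row per cell. If `config$out_dir` is set,
#' each completed cell is written to disk immediately and cells whose
#' file already exists are reloaded instead of recomputed, making long
#' runs resumable.
#'
#' @param config A [study_config()].
#' @param progress Passed to [run_condition()].
#' @return Data frame of condition summaries (one row per cell).
#' @export
run_study <- function(config, progress = 0) {
  conditions <- condition_grid(config)
  out <- list()
  use_disk <- !is.null(config$out_dir)
  if (use_disk && !dir.exists(config$out_dir)) {
    ok <- dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(config$out_dir))
      stop("cannot create output directory: ", config$out_dir)
  }
  for (cond in conditions) {
    for (est in config$estimators) {
      key <- cell_key(cond, est)
      path <- if (use_disk) file.path(config$out_dir,
                                      paste0(key, ".csv")) else NULL
      if (use_disk && file.exists(path)) {
        out[[key]] <- utils::read.csv(path)
        next
      }
      res <- run_condition(cond, est, config$replications,
                           config$master_seed, alpha = config$alpha,
                           priors = config$priors, mcmc = config$mcmc,
                           progress = progress)
      out[[key]] <- res$summary
      if (use_disk) write_records(res$summary, path)
    }
  }
  if (length(out) == 0) return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (use_disk)
    utils::write.csv(res, file.path(config$out_dir, "summaries.csv"),
                     row.names = FALSE)
  res
}

#' The prior-sensitivity grid
#'
#' The nine prior settings of the sensitivity experiment. Location priors
#' are normal `(mean, sd)`; SD priors are gamma `(shape, rate)`. Settings
#' 8 and 9 only alter the random model's between-person autocorrelation
#' SD prior and so have no fixed-model column entries.
#'
#' @return A data frame with one row per prior setting.
#' @export
prior_sensitivity_grid <- function() {
  data.frame(
    test = 1:9,
    fixed_mu_mean   = c(0, 0, 1, 1, 0, 0, 0, NA, NA),
    fixed_mu_sd     = c(2, 5, 2, 5, 2, 2, 2, NA, NA),
    fixed_se_shape  = c(2, 2, 2, 2, 1, 1, 2, NA, NA),
    fixed_se_rate   = c(2, 2, 2, 2, 1, 2, 1, NA, NA),
    rand_g00_mean   = c(0, 0, 1, 0, 0, 0, 0, 0, 0),
    rand_g00_sd     = c(2, 5, 2, 2, 2, 2, 2, 2, 2),
    rand_su0_shape  = c(2, 2, 2, 1, 1, 2, 2, 2, 2),
    rand_su0_rate   = c(2, 2, 2, 1, 2, 2, 2, 2, 2),
    rand_se_shape   = c(2, 2, 2, 2, 2, 1, 1, 2, 2),
    rand_se_rate    = c(2, 2, 2, 2, 2, 1, 2, 2, 2),
    rand_su1_shape  = c(2, 2, 2, 2, 2, 2, 2, 1, 1),
    rand_su1_rate   = c(2, 2, 2, 2, 2, 2, 2, 1, 2))
}

#' Run the prior-sensitivity experiment
#'
#' Re-runs the Bayesian estimators on the same panels (common random
#' numbers) under each prior setting of [prior_sensitivity_grid()], at
#' the sensitivity condition: population intercept 0, between-person
#' autocorrelation SD 0.40, T = N = 10, population autocorrelation 0.
#' The fixed model is run for settings 1-7, the random model for all 9.
#'
#' @param R Replications per prior setting.
#' @param master_seed Integer master seed.
#' @param mcmc An [mcmc_settings()].
#' @param estimators Subset of `c("BAY-F", "BAY-R")`.
#' @param condition Override of the sensitivity condition.
#' @param progress Print a line per completed setting if `TRUE`.
#' @return Data frame with one row per (estimator, prior setting):
#'   the mean population-autocorrelation and mean location estimates
#'   across replications.
#' @export
run_prior_sensitivity <- function(R = 50, master_seed = 1L,
                                  mcmc = mcmc_settings(),
                                  estimators = c("BAY-F", "BAY-R"),
                                  condition = mlar1_condition(
                                    T = 10, N = 10, gamma01 = 0,
                                    sigma_u1 = 0.40),
                                  progress = FALSE) {
  grid <- prior_sensitivity_grid()
  panels <- lapply(seq_len(R), function(r)
    generate_panel(condition,
                   seed = replication_seed(master_seed, condition, r)))
  mseeds <- vapply(seq_len(R), function(r)
    replication_seed(master_seed, condition, r, stream = 1), 0L)
  rows <- list()
  for (est in estimators) {
    tests <- if (est == "BAY-F") which(!is.na(grid$fixed_mu_mean))
             else grid$test
    for (tt in tests) {
      gr <- grid[grid$test == tt, ]
      pr <- if (est == "BAY-F")
        prior_spec(mu_prior = c(gr$fixed_mu_mean, gr$fixed_mu_sd),
                   sigma_e_prior = c(gr$fixed_se_shape, gr$fixed_se_rate))
      else
        prior_spec(gamma00_prior = c(gr$rand_g00_mean, gr$rand_g00_sd),
                   sigma_u0_prior = c(gr$rand_su0_shape, gr$rand_su0_rate),
                   sigma_e_prior = c(gr$rand_se_shape, gr$rand_se_rate),
                   sigma_u1_prior = c(gr$rand_su1_shape, gr$rand_su1_rate))
      g01 <- mu <- rep(NA_real_, R)
      for (r in seq_len(R)) {
        fit <- if (est == "BAY-F")
          fit_bayes_fixed(panels[[r]], priors = pr, settings = mcmc,
                          seed = mseeds[r])
        else
          fit_bayes_random(panels[[r]], priors = pr, settings = mcmc,
                           seed = mseeds[r])
        g01[r] <- fit$gamma01_hat
        mu[r] <- if (est == "BAY-F") {
          pi <- fit$per_individual
          mean(pi$mean[pi$parameter == "mu"])
        } else fit$gamma00_hat
      }
      rows[[paste(est, tt)]] <- data.frame(
        estimator = est, test = tt,
        mean_gamma01_hat = mean(g01), mean_mu_hat = mean(mu),
        R = R)
      if (progress)
        message(sprintf("prior setting %d (%s): mean gamma01_hat %.4f",
                        tt, est, mean(g01)))
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Read a study configuration from a YAML or JSON file
#'
#' The file may set any of the arguments of [study_config()] (grid value
#' lists, `replications`, `estimators`, `alpha`, `master_seed`,
#' `out_dir`) plus nested `priors` and `mcmc` blocks mirroring
#' [prior_spec()] and [mcmc_settings()].
#'
#' @param path File path; format chosen by extension
#'   (`.yml`/`.yaml` or `.json`).
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw[intersect(names(raw),
                        c("T_values", "N_values", "sigma_u1_values",
                          "gamma01_values", "replications", "estimators",
                          "alpha", "master_seed", "out_dir"))]
  if (!is.null(raw$priors)) args$priors <- do.call(prior_spec, raw$priors)
  if (!is.null(raw$mcmc)) args$mcmc <- do.call(mcmc_settings, raw$mcmc)
  do.call(study_config, args)
}
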