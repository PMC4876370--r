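# Outcome measures of the Monte-Carlo study, computed from a table of
# per-replication fit records. A record carries the population
# autocorrelation estimate, its standard error, the between-person SD
# estimate, the confidence or credible interval, the rejection decision,
# and the computational-problem tallies for that replication.

#' Assemble a replication record from a fitted model
#'
#' Normalizes any of the four fit objects into the one-row data frame
#' used by the outcome measures.
#'
#' @param fit A fit from [fit_mle_fixed()], [fit_mle_random()],
#'   [fit_bayes_fixed()] or [fit_bayes_random()].
#' @param estimator Estimator label (`"MLE-F"`, `"MLE-R"`, `"BAY-F"` or
#'   `"BAY-R"`).
#' @param r Replication index.
#' @return A one-row data frame.
#' @export
replication_record <- function(fit, estimator, r) {
  ci <- fit$ci_gamma01
  rejected <- if (!is.null(fit$rejected_h0)) fit$rejected_h0
              else !is.na(ci[1]) && (ci[1] > 0 || ci[2] < 0)
  data.frame(
    estimator = estimator, r = as.integer(r),
    gamma01_hat = fit$gamma01_hat,
    se_gamma01 = fit$se_gamma01,
    sigma_u1_hat = fit$sigma_u1_hat,
    ci_lower = ci[1], ci_upper = ci[2],
    rejected_h0 = rejected,
    n_nonconverged = if (!is.null(fit$n_nonconverged))
      fit$n_nonconverged else 0L,
    n_nonstationary = if (!is.null(fit$n_nonstationary))
      fit$n_nonstationary else 0L,
    n_individuals = if (!is.null(fit$n_individuals)) fit$n_individuals
      else length(fit$phi_individual),
    converged = if (!is.null(fit$converged)) isTRUE(fit$converged) else TRUE)
}

usable <- function(records) {
  if (nrow(records) == 0) stop("no replication records")
  keep <- records$converged & is.finite(records$gamma01_hat)
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("no usable replication records")
  out
}

#' Bias of the population-autocorrelation estimate
#'
#' Mean of the replication estimates minus the generating value.
#'
#' @param records Replication-record data frame.
#' @param gamma01_true Generating population autocorrelation.
#' @return A single number.
#' @export
bias_gamma01 <- function(records, gamma01_true) {
  mean(usable(records)$gamma01_hat) - gamma01_true
}

#' Bias of the between-person SD estimate
#'
#' Mean of the replication estimates of the between-person
#' autocorrelation SD minus the generating value. For fixed estimators
#' the per-replication estimate is the sample SD (n-1 denominator) of the
#' individual autocorrelation estimates.
#'
#' @param records Replication-record data frame.
#' @param sigma_u1_true Generating between-person SD.
#' @return A single number.
#' @export
bias_sigma_u1 <- function(records, sigma_u1_true) {
  mean(usable(records)$sigma_u1_hat) - sigma_u1_true
}

#' Empirical SD of the population-autocorrelation estimate
#'
#' Standard deviation (n-1 denominator) of the estimates across
#' replications: the Monte-Carlo measure of estimator variability.
#'
#' @param records Replication-record data frame.
#' @return A non-negative number.
#' @export
empirical_sd <- function(records) {
  stats::sd(usable(records)$gamma01_hat)
}

#' Bias of the standard error
#'
#' Mean of the reported standard errors minus the empirical SD of the
#' estimates: positive values mean the estimator overstates its own
#' variability. For fixed estimators the reported SE of a replication is
#' the mean of the individual standard errors.
#'
#' @param records Replication-record data frame.
#' @return A single number.
#' @export
bias_se <- function(records) {
  u <- usable(records)
  mean(u$se_gamma01) - stats::sd(u$gamma01_hat)
}

#' Empirical rejection rate
#'
#' Fraction of replications whose interval excludes zero: the actual
#' type-I error rate when the generating population autocorrelation is 0,
#' and the power otherwise.
#'
#' @param records Replication-record data frame.
#' @return A number in `[0, 1]`.
#' @export
epr <- function(records) {
  mean(usable(records)$rejected_h0)
}

#' Percentile interval of the estimates across replications
#'
#' The 2.5th and 97.5th percentiles of the population-autocorrelation
#' estimates across replications, using the linear-interpolation quantile
#' definition (R type 7).
#'
#' @param records Replication-record data frame.
#' @return Length-2 numeric vector `(lower, upper)`.
#' @export
interval_estimate <- function(records) {
  q <- stats::quantile(usable(records)$gamma01_hat,
                       probs = c(0.025, 0.975), type = 7, names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Summarize one condition's replications
#'
#' Assembles every outcome measure plus the computational-problem tallies
#' into a one-row data frame. Non-stationary individual predictions are
#' counted per individual prediction (not per panel): the percentage is
#' `100 * (predictions with |phi| > 1) / (total predictions)`.
#' Replications with a failed fit are dropped from the measures and
#' reported through `R_effective`.
#'
#' @param records Replication-record data frame for one condition and one
#'   estimator.
#' @param condition The generating [mlar1_condition()].
#' @return A one-row data frame of class `mlar1_condition_summary`.
#' @export
summarize_condition <- function(records, condition) {
  u <- usable(records)
  ie <- interval_estimate(u)
  total_pred <- sum(u$n_individuals)
  total_attempted <- sum(records$n_individuals)
  out <- data.frame(
    estimator = u$estimator[1],
    T = condition$T, N = condition$N,
    gamma01 = condition$gamma01, sigma_u1 = condition$sigma_u1,
    bias_gamma01 = bias_gamma01(u, condition$gamma01),
    bias_sigma_u1 = bias_sigma_u1(u, condition$sigma_u1),
    empirical_sd = empirical_sd(u),
    bias_se = bias_se(u),
    epr = epr(u),
    interval_lower = ie[["lower"]], interval_upper = ie[["upper"]],
    mean_gamma01_hat = mean(u$gamma01_hat),
    pct_nonconverged = 100 * sum(records$n_nonconverged) /
      max(total_attempted, 1L),
    pct_nonstationary = 100 * sum(u$n_nonstationary) /
      max(total_pred, 1L),
    R_effective = nrow(u), R_attempted = nrow(records))
  class(out) <- c("mlar1_condition_summary", class(out))
  out
}
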