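# mlar1sim

Monte-Carlo machinery for comparing estimators of the autocorrelation in
**multilevel AR(1) models** — the workhorse model for intensive
longitudinal data, where short time series (ecological momentary
assessment, daily diaries) are nested within a modest number of
individuals and the scientific quantity is *inertia*: the lag-1
autocorrelation of a psychological state and its spread across people.

## The model and the estimators

Level 1 (time points within person *n*):

    y[t,n] = mu_n + phi_n * (y[t-1,n] - mu_n) + e[t,n],   e ~ N(0, sigma_e)

Level 2 (people): mu_n = gamma00 + U0_n and phi_n = gamma01 + U1_n, with
U0 ~ N(0, sigma_U0), U1 ~ N(0, sigma_U1). The target of inference is the
population autocorrelation gamma01 and its between-person SD sigma_U1.

The package implements four estimators of gamma01 and the apparatus to
race them:

* **MLE-F** — per-individual exact stationary Gaussian AR(1) maximum
  likelihood (estimates constrained to (-1, 1) by construction),
  aggregated by averaging estimates and standard errors;
* **MLE-R** — restricted maximum likelihood for the linear mixed model
  with a fixed and random intercept and slope on the lagged score
  (uncorrelated random effects), written here as a profiled REML
  criterion in closed-form per-individual algebra and verified against
  `lme4` to below 1e-4;
* **BAY-F / BAY-R** — fixed and hierarchical Bayesian models sampled by
  adaptive Metropolis-within-Gibbs under Berger's symmetrized reference
  prior `1/(pi*sqrt(1-phi^2))` for the autocorrelation, normal(0,2) and
  Gamma(2,2) priors elsewhere, with split-chain Rhat bookkeeping.

Around them: a fully seeded panel generator (individual autocorrelations
from a (-1,1)-truncated normal, series started in the stationary
distribution), the outcome measures of estimator quality (bias of
gamma01 and sigma_U1, empirical SD, bias of the SE, empirical rejection
rate, percentile interval estimates, non-convergence and
non-stationarity tallies), and a deterministic, resumable runner over
the fully crossed 40-condition design (T and N in {10, 25}, sigma_U1 in
{0.25, 0.40}, gamma01 in {-0.6, ..., 0.6}).

## Worked example

```r
library(mlar1sim)

cond  <- mlar1_condition(T = 25, N = 25, gamma01 = 0.3, sigma_u1 = 0.25)
panel <- generate_panel(cond, seed = 1)
fit   <- fit_mle_random(panel)
fit
#> Random-model REML fit (random intercept + random slope on lag)
#>   gamma01_hat = 0.3821 (SE 0.0545), 95% CI [0.2695, 0.4948]
#>   sigma_u0 = 0.3238, sigma_u1 = 0.1939, sigma_e = 1.0063
#>   0 individual prediction(s) outside the stationary region
```

One panel: the population autocorrelation (true 0.3) is estimated at
0.38 with a t-based CI using N-2 degrees of freedom; this particular
draw of 25 individuals happens to sit high (their true phi average
0.335). Monte-Carlo properties come from replication:

```r
res <- run_condition(cond, "MLE-R", R = 200, master_seed = 1)
round(res$summary[, c("bias_gamma01", "empirical_sd", "bias_se", "epr",
                      "pct_nonstationary")], 4)
#>   bias_gamma01 empirical_sd bias_se   epr pct_nonstationary
#> 1       0.0032       0.0623 -0.0057 0.995                 0
```

Over 200 seeded replications of this easy condition the estimator is
nearly unbiased (+0.003), its reported SE slightly understates the true
variability (-0.006, the characteristic direction for REML here), power
to reject gamma01 = 0 is 99.5%, and no individual prediction leaves the
stationary region. Runs are deterministic in `(condition, master_seed)`
and a shorter run is an exact row-prefix of a longer one.

The numbered scripts in `analysis/` (01 panels, 02 ML grid, 03 Bayesian
arm + convergence table, 04 prior sensitivity, 05 report/figures) step
through the whole study at desk scale and write tidy CSVs under
`results/`.

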