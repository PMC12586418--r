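# copboost

Boosted distributional copula regression for survival data with **dependent
right-censoring**.

## What problem this solves

Right-censored time-to-event analyses almost universally assume that the
censoring time `C` is conditionally independent of the survival time `T`.
In routine observational data (registry follow-up, loss to follow-up driven
by disease severity or by good health) that assumption is both untestable
and often wrong, and it biases Kaplan–Meier, Cox and parametric AFT
estimates in unknowable directions.

`copboost` instead models the pair jointly: parametric margins for `T` and
`C` (Weibull or log-normal) are coupled by a one-parameter copula (Clayton,
Gaussian or Gumbel), and **every** distribution parameter — location and
scale of both margins plus the copula dependence parameter — gets its own
additive predictor `η_k(x)` behind a link function.  Writing
`u = F_T(y|x)`, `v = F_C(y|x)` and `h` for the copula's conditional
h-functions, the observed data `(Y, δ) = (min(T,C), 1{T ≤ C})` contribute

    δ = 1 :  f_T(y|x) [ 1 − h_{C|T}(v | u; θ(x)) ]
    δ = 0 :  f_C(y|x) [ 1 − h_{T|C}(u | v; θ(x)) ]

to the likelihood.  Estimation is by **non-cyclic component-wise gradient
boosting**: per iteration the score of every predictor is computed, simple
least-squares base-learners (one per covariate, plus an intercept learner)
compete within each parameter by residual sum of squares, the per-parameter
winners compete across parameters by the actual risk reduction of a
`ν`-scaled tentative update, and only the overall best update is committed.
Early stopping on a validation set yields data-driven variable selection and
works for `p > n`.  A boosted distributional Weibull/log-normal AFT model
(independent censoring) is included as the standard benchmark.

Intended users: biostatisticians and methods researchers who need
dependence-aware survival regression with variable selection, or a testbed
for evaluation under dependent censoring (model-based IPCW Brier score,
integrated absolute error against simulation truth oracles).

## Worked example

```r
library(copboost)

# Scenario: strong positive T–C dependence driven by covariate x5,
# Weibull margins, ~20% censoring, 10 shared covariates (5 informative).
st  <- simulation_setting(setting = 1, margin = "weibull", copula = "gaussian",
                          censoring = 20, p_per_parameter = 10,
                          n = 1000, seed = 1010)
rep <- simulate_replicate(st)          # train / validation / test triple

spec <- model_spec(margin_spec("weibull"), margin_spec("weibull"),
                   copula_spec("gaussian"))
fit <- fit_boost(spec, rep$train$data,
                 boost_config(nu = 0.01, mstop_max = 15000),
                 data_val = rep$val$data)
fit
#> <boost_fit> copula model, 15000 iterations run, m_stop = 14968
#>   risk: 762.6287 (offset) -> -396.3424 (m_stop)

round(coef(fit)$beta[1:5, ], 2)
#>     mu_T sigma_T  mu_C sigma_C  rho
#> x1  2.05    0.00 -0.12    0.00 0.00
#> x2  0.00   -0.01 -1.07    0.49 0.00
#> x3  1.01    0.70 -0.06    0.00 0.00
#> x4 -0.01    0.00  1.65   -0.06 0.00
#> x5  0.03    0.00  0.00    0.01 1.07
```

The informative covariates are picked out with close-to-true coefficients
(truth: `mu_T` = 2·x1 + 1·x3, `sigma_T` = 0.7·x3, `mu_C` = −1·x2 + 1.5·x4,
`sigma_C` = 0.5·x2, dependence = 1.5·x5); pure-noise covariates keep exact
zeros.  Evaluation with dependence-aware weights:

```r
ev <- evaluate_fit(fit, rep$test$data, truth = rep$test$truth)
#> Warning: censoring-survival weights floored at 0.0001 in 7503 cells
round(c(brier = ev$brier_summary, iae_surv = ev$iae_survival,
        iae_cens = ev$iae_censoring), 3)
#>    brier iae_surv iae_cens
#>    0.067    0.029    0.264
```

(The warning is the documented IPCW guard: deep in the time tail the
model's conditional censoring survival underflows the 1e-4 weight floor.)

`brier` is the censoring-weighted Brier score averaged over the observed
test times with the model's own conditional censoring survival
`Ĝ(t|x)` as IPCW weights; the `iae` values are time-integrated absolute
errors of the fitted survival (and censoring-survival) curves against the
simulator's exact truth oracle — lower is better everywhere.

There is also a command line (`inst/cli/copboost`) with `simulate`, `fit`,
`evaluate` and `select-model` subcommands operating on CSV survival tables
(columns `y`, `delta`, covariates), and `cv_predictive_loglik()` ranks
margin × copula candidates by 10-fold held-out log-likelihood for real-data
model choice.

## Package layout

* `R/margins.R`, `R/copulas.R` — margin and copula families, links,
  h-functions, analytic derivatives, conditional-inversion sampling.
* `R/likelihood.R` — observed-data likelihood, predictor-scale scores, AFT
  benchmark loss, conditional censoring survival.
* `R/boosting.R` + `src/boost_engine.cpp` — non-cyclic boosting engine
  (compiled hot loop mirroring the exported R reference implementation),
  offsets, cross-validation utilities.
* `R/simulate.R` — scenario generator with truth oracles.
* `R/evaluate.R` — KM censoring estimator, IPCW Brier score, IAE.
* `R/study.R` — replicated simulation experiments.
* `R/cli.R`, `R/io.R` — command line and CSV/JSON round-trip I/O.
* `vignettes/copula-boosting-methods.Rmd` — model, assumptions, numerical
  choices and design rationale.
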