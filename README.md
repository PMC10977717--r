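# bayesfcr

Bayesian variable selection for **discrete survival outcomes** in
high-dimensional settings. `bayesfcr` is aimed at biostatisticians and
genomics researchers whose time-to-event data are recorded on an interval
scale — relapse assessed at scheduled follow-up visits, survival grouped
into clinical review periods — and who want to identify, from thousands of
candidate features (e.g. gene expression), the few associated with the
discrete hazard, with full posterior uncertainty.

## The model

Time is split into `K + 1` intervals; the discrete hazard
`π_ik = Pr(Y_i = k | Y_i ≥ k, x_i)` follows a forward continuation ratio
(FCR) model with a complementary log-log link,

```
log(−log(1 − π_ik)) = α_k + x_i' D_γ β,    k = 1, …, K,
```

which is a grouped proportional hazards model whose coefficients match an
underlying Cox model. Censored data are expanded into independent
Bernoulli records (one per subject × at-risk interval), under either the
censor-at-interval-start convention (default) or censor-at-end.
Regularization and selection come from the hierarchical prior

```
β_m | λ ~ Laplace(0, 1/λ)      (Bayesian LASSO)
λ ~ Gamma(a, b)                (penalty hyperprior)
γ_m ~ Bernoulli(s)             (variable inclusion indicators)
α_k ~ Normal(0, σ²)
```

sampled by a Metropolis-within-Gibbs scheme with exact conditionals for
`γ` and `λ` (C++ core). Features are then selected by credible/HPD
intervals, posterior inclusion probabilities `Pr(γ|D) > 0.5`, or Bayes
factors (`BF > 5`) for `|β| > ε`, `|γβ| > ε` or `γ = 1`, all with
closed-form prior odds. A simulation engine benchmarks every rule against
a known truth set (TPR, TNR, PPV, NPV, FDR), and classic Gelman–Rubin
PSRF diagnostics flag non-convergence.

## Worked example

Simulate a dataset in the benchmark's default regime — 250 subjects, 100
block-correlated standardized features, five effects at `+log 2` and five
at `−log 2`, exponential event and censoring times, five balanced
intervals — then fit with a sparse prior (`s = 0.01`) and select by the
γ Bayes factor:

```r
library(bayesfcr)

design <- simulation_design(n = 250, p = 100, n_datasets = 1)
sim <- simulate_dataset(design, seed = 42)
sim$data
#> Discrete survival data: 250 subjects, 100 features, 5 time intervals
#> Events: 165 (66% uncensored)

fit <- fcr_blasso(sim$data, fcr_model_spec(s = 0.01),
                  mcmc_schedule(n_saved_total = 999), seed = 7)
fit
#> Bayesian LASSO FCR fit
#>   data: N = 250 , P = 100 , K = 4 ( 648 Bernoulli records )
#>   prior inclusion s = 0.01 ; censoring convention: start
#>   chains: 3 x 333 retained draws (thin 3 )
#>   posterior mean lambda: 1.516

sel <- select_features(fit, method = "BF_gamma")
dplyr::filter(sel, selected)
#> 11 features selected: the ten planted ones (feat001, feat011, …,
#> feat091, all with every posterior draw including them, BF = Inf)
#> plus one false positive (feat047, BF = 7.7)

compute_metrics(which(sel$selected), sim$truth$idx, p = 100)
#>   discoveries tpr    tnr    ppv npv    fdr
#> 1          11   1 0.9889 0.9091   1 0.0909
```

All ten true features are recovered (TPR = 1) with one spurious call
(FDR = 0.09 on this single dataset). `tidy(fit)` returns a broom-style
parameter table, `glance(fit)` a one-row fit summary including the PSRF
count, `autoplot(fit)` a caterpillar plot of effective coefficients, and
`run_simulation_study()` repeats the whole pipeline over replicate
datasets and selection rules. `preprocess_features()` provides the usual
expression-matrix preparation (missingness, low-unique-value,
correlation and variance filters, standardization), and `exec/bayesfcr`
exposes `simulate` / `fit` / `select` / `study` / `preprocess`
subcommands for shell use.

See the vignette (`vignettes/bayesian-lasso-fcr.Rmd`) for the model,
sampler, selection rules and design choices in detail.

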