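# gposterior

Robust quasi-Bayesian inference for the normal location–scale model using
gamma-divergence (and density-power-divergence) posteriors, with
contamination-robust objective priors.

## The problem

Real univariate measurements are often a clean Gaussian signal plus a
fraction of gross outliers:

$$g(x) = (1-\varepsilon)\,N(\mu, \sigma^2) + \varepsilon\,\delta(x),$$

with a contamination ratio ε that need not be small. The ordinary posterior
mean (equivalently, the MLE) is wrecked by such contamination. Replacing the
log-likelihood in Bayes' formula with the **gamma loss**

$$q^{(\gamma)}(x;\theta) = \frac{1}{\gamma} f_\theta(x)^\gamma
  \Big(\int f_\theta^{1+\gamma}\Big)^{-\gamma/(1+\gamma)}$$

gives a quasi-posterior
$\pi^{(\gamma)}(\theta\mid X^n) \propto \exp\{\sum_i q^{(\gamma)}(X_i;\theta)\}\pi(\theta)$
whose mean smoothly ignores observations in the model's tail. The package's
focus is the *objective-prior* side of this construction: the reference
prior $\pi_R \propto \det\{J(\theta)\}^{1/2}$ and the moment-matching prior
(which makes the posterior mean agree with the frequentist
minimum-divergence estimator to o(1/n)) normally depend on the unknown
contamination, but for the gamma loss they reduce — whenever the contaminant
lies in the model's tail — to clean-model closed forms, for the normal model

$$\pi_R^{(\gamma)}(\mu,\sigma) \propto \sigma^{-3+1/(1+\gamma)}, \qquad
  \pi_M^{(\gamma)}(\mu,\sigma) \propto \sigma^{-(\gamma+7)/\{2(1+\gamma)\}},$$

no matter how large ε is. The package implements the losses and
cross-entropies, minimum-divergence estimation, these priors (closed-form
and numerically derived), importance-sampling posterior means with a
deterministic grid oracle, sandwich-matrix contamination diagnostics, the
asymptotic-relative-efficiency curve for choosing γ, and a reproducible
bias/MSE simulation harness. See the methods vignette
(`vignettes/gamma-posterior-methods.Rmd`) for the model, assumptions and
numerical choices.

## Worked example

Draw 100 observations from 0.8·N(0,1) + 0.2·N(6,1) and estimate (μ, σ):

```r
library(gposterior)

spec <- contamination_spec(epsilon = 0.2, nu = 6)
x <- sample_contaminated(spec, 100, seed = 42)

minimize_cross_entropy(x, normal_model(), kl_loss())          # the MLE
#> <estimator_result> KL
#>      mu   sigma
#> 1.64732 2.81661

minimize_cross_entropy(x, normal_model(), gamma_loss(0.5))    # robust
#> <estimator_result> gamma(0.5)
#>       mu    sigma
#> 0.173137 1.097450

loss <- gamma_loss(0.5)
qp <- quasi_posterior(x, normal_model(), loss,
                      normal_closed_form_prior("reference", loss))
importance_sampling_mean(qp, is_config(n_draws = 2e5, seed = 1))
#> <posterior_summary>
#>       mu    sigma
#> 0.359309 1.534810
#>   ESS 1089.3 / 200000 draws (seed 1)
```

The MLE is dragged to (1.65, 2.82) by the outlier cluster; the
gamma-posterior point estimate stays near the clean component (this
particular seed draws an unusually heavy contamination share, so the
posterior mean sits a little above the point estimate). Note the effective
sample size: on contaminated data the moment-based proposal is a poor match
for the robust posterior, so many draws are needed; the deterministic
cross-check

```r
grid_posterior_mean(qp, c(-1, 2.5), c(0.3, 4.5))
#>        mu     sigma
#> 0.3599336 1.5160907
```

agrees with the sampler. Choosing the tuning by asymptotic relative
efficiency:

```r
are_normal(0.3)
#> <are_result> gamma = 0.3: ARE = 0.273187 (closed_form, p = 2)
choose_gamma_for_are(0.95)
#> [1] 0.01032107
```

(Two efficiency conventions exist and disagree; `are_normal(..., method =
"sandwich")` recomputes the determinant-ratio efficiency from first
principles — see the vignette.)

A thin command-line front end over the same functions is installed at
`inst/cli/gposterior-cli.R` (subcommands `estimate`, `posterior-mean`,
`are`, `gamma-for-are`, `simulate`, `reproduce`, `sweep`).

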