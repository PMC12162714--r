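# bjlcm — Bayesian shared-parameter joint latent class models

`bjlcm` is an R package for jointly modelling a repeatedly measured
longitudinal marker and a time-to-event outcome in a population made of
latent subgroups. It is aimed at biostatisticians analysing cohort data
(e.g. a cognitive score and time to dementia) where (a) subjects plausibly
fall into classes with different marker trajectories *and* different event
risks, and (b) the two outcomes remain dependent within a class — so the
basic joint latent class model's conditional-independence assumption is too
strong.

## The model

For subject $i$ with latent class $c_i \in \{1,\dots,G\}$:

* membership: $P(c_i = g \mid W_i) = \dfrac{\exp(\psi_{g0} + W_i^\top\psi_g)}
  {\sum_k \exp(\psi_{k0} + W_i^\top\psi_k)}$, class $G$ as zero reference;
* longitudinal (given $c_i = g$): $y_i(t) \sim N(\mu_{ig}(t), \sigma_g^2)$,
  $\mu_{ig}(t) = X_i(t)^\top\beta_g + Z_i(t)^\top b_{ig}$,
  $b_{ig} \sim N(0, \Sigma_g)$ with diagonal $\Sigma_g$;
* hazard (given $c_i = g$): $h_{ig}(t) = \phi_{g0}\, t^{\phi_{g0}-1}
  \exp\{\phi_{g1} + \tilde W_i^\top \gamma_g + \alpha_g\, \mu_{ig}(t)\}$
  (current-value association; current-slope and no-association variants are
  available).

Estimation is fully Bayesian: the class indicators are marginalized out and
the resulting smooth posterior is sampled with a built-in No-U-Turn sampler
over analytic C++ gradients. Multimodality is handled by running several
independently initialized chains and selecting the dominant one by a
truncated-harmonic-mean estimate of each chain's marginal-likelihood
weight. Class indicators are then drawn exactly from their full
conditional; the number of classes is chosen by forward selection over
PSIS-LOO/WAIC z-tests combined with an effective-class-size guard. The
random-effect variances carry a purpose-built penalized prior
$\prod_k \mathrm{Ga}(\Sigma_{g,kk}\mid\alpha_b,\alpha_b)\,
\exp(-\lambda/\sqrt{\sum_k \Sigma_{g,kk}})$ that keeps mixtures away from
degenerate tiny-variance solutions. See the vignette
(`vignettes/shared-parameter-jlcm.Rmd`) for the method account.

## Worked example

Simulate a two-class benchmark dataset (80 subjects, covariate-dependent
membership), fit the correctly specified model with two short chains, and
compare the estimates with the generating values:

```r
library(bjlcm)

sim  <- simulate_dataset(sim_design("setting2_scenario3", n = 80, seed = 11))
spec <- scenario_spec(G = 2, membership_model = 2)   # membership ~ male + age
fit  <- jlcm_fit(sim$data, spec, jlcm_priors(),
                 jlcm_chains(M = 2, iter = 600, warmup = 300, thin = 1,
                             base_seed = 3, rhat_threshold = 1.1))
print(fit)
#> Shared-parameter JLCM fit, G = 2
#>   selected chain: 1 of 2 (log evidence -831.7)
#>   LOOIC 1007.9 (SE 89.1)   WAIC 996.8 (SE 88.1)
#>   effective classes (threshold 1%): 2
#>   class shares: 35.0%, 65.0%
summary(fit)[c(1, 10, 11, 20), ]
#>         param    mean     sd    q2.5   q97.5
#> 1   beta[1,0]  7.9736 0.3918  7.1631  8.7890
#> 10   alpha[1]  0.3320 0.1015  0.1457  0.5234
#> 11  beta[2,0] -8.0819 0.0999 -8.2713 -7.8885
#> 20   alpha[2]  0.1133 0.0354  0.0474  0.1739
classification_accuracy(fit, sim$truth$labels)
#> [1] 0.975
```

The generating values here are trajectory intercepts $\pm 8.03$ and
association strengths $0.38$ / $0.08$: both classes are recovered (class 1
is reported first by the canonical decreasing-intercept convention), the
association between the marker level and the hazard is clearly positive in
class 1, and 97.5% of subjects are assigned to their true class by the MAP
rule. `fit$looic` / `fit$waic` carry the pointwise vectors needed by
`forward_select()` when comparing candidate numbers of classes, and
`write_fit_bundle()` saves draws, diagnostics, membership probabilities and
provenance as plain-text artifacts.

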