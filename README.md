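# uvrdefense

Bayesian hierarchical analysis of how ultraviolet radiation (UVR) affects
kairomone-inducible defenses in juvenile *Daphnia pulex* — for ecologists
and ecotoxicologists analysing predator-induced trait data with maternal
clustering, and for anyone who needs a fully seeded, self-contained
reference implementation of the underlying models.

Juvenile *D. pulex* develop neckteeth (0–5 small dorsal spines) and a
pedestal (ordinal classes A &lt; B &lt; C) when they sense kairomones from
predatory *Chaoborus* larvae. The package models the two traits jointly,
per instar, as a bivariate hierarchical GLM sharing a treatment design
$x_i$ (clone × kairomone × UVR, two-way interactions):

- neckteeth: $k_i \sim \mathrm{Binomial}(5, \mathrm{logit}^{-1}(x_i^\top\beta^N + u^N_{m(i)}))$
- pedestal: $P(c_i \le k) = \mathrm{logit}^{-1}(\tau_k - x_i^\top\beta^P - u^P_{m(i)})$, $\tau_1 < \tau_2$

with per-mother random intercepts $u_m \sim N(0, \sigma^2)$ and
$N(0, 10)$ priors on all coefficients. Body length, body width and spina
length are modelled jointly as a zero-truncated trivariate Gaussian with
mother effects and unstructured residual covariance. Inference is MCMC
(slice-within-Gibbs; the defense scan is compiled) with rank-normalized
split-$\hat R$ / bulk-ESS diagnostics, 95% credible-interval "strong
effect" calls, and Savage–Dickey density-ratio evidence for point nulls.
A seeded synthetic-data generator emulates both of the study's
experiments (a kairomone-effectivity trial and a 2-clone factorial
kairomone × UVR experiment), so the entire pipeline is testable offline.

## Worked example

```r
library(uvrdefense)

gen <- generator_config(seed = 1)           # study-calibrated defaults
juv <- simulate_main_experiment(gen)        # 603 juvenile records, 48 mothers

fit <- fit_defense_model(juv[juv$instar == 2, ],
                         config = sampler_preset("main", seed = 1))
max(check_identifiability(fit$draws)$rhat)
#> [1] 1.005201
head(effect_summary_table(fit)[, c("parameter", "median", "ci95_low",
                                   "ci95_high", "strong")], 4)
#>       parameter     median  ci95_low   ci95_high strong
#> 1 N_(Intercept) -2.5816917 -3.213325 -2.05516852   TRUE
#> 2    N_cloneUNI -0.8476507 -1.797482  0.03016411  FALSE
#> 3  N_kairomone1  1.6973662  1.034169  2.46050241   TRUE
#> 4        N_uvr1 -0.9018135 -2.096503  0.13318424  FALSE
```

`N_kairomone1` is the kairomone effect on the instar-2 neckteeth count on
the log-odds scale: positive and with a 95% credible interval excluding 0
("strong"), i.e. kairomone exposure induces neckteeth in the second
instar, as it should under the generator's truth (+2.4). The
`run_effectivity_analysis()` / `run_main_analysis()` front ends wrap
simulation or CSV ingest, fitting, convergence gating, effect tables,
Savage–Dickey hypothesis tests and forest plots into an artifact
directory; `make_report()` collates it into one markdown report, and
`inst/cli/uvrdefense-cli.R` exposes `simulate` / `fit` / `report`
subcommands from a shell.

See `vignettes/uvrdefense-methods.Rmd` for the full model description,
priors, sampler design, generator calibration and limitations.

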