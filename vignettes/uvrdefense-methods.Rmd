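---
title: "Models and methods: UVR effects on inducible defenses in Daphnia pulex"
author: "uvrdefense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: UVR effects on inducible defenses in Daphnia pulex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvrdefense)
```

## The scientific problem

Juvenile *Daphnia pulex* develop morphological defenses — neckteeth (small
spines at the dorsal head margin, counted 0–5) and a pedestal at their base
(scored ordinally A &lt; B &lt; C) — when they detect kairomones released by
feeding *Chaoborus* larvae. Ultraviolet radiation (UV-A) is a second,
abiotic stressor that can suppress this induction, either by degrading the
kairomone in the water or by acting directly on the animals. `uvrdefense`
implements a Bayesian hierarchical analysis of both questions:

1. a **kairomone-effectivity trial**: kairomone suspensions exposed to UVR
   or PAR for 2/4/6/8 h (plus a kairomone-free control), scored in
   2nd-instar offspring of mothers placed in the treated media; and
2. a **main factorial experiment**: two clones (UNI, P5) crossed with
   kairomone and UVR exposure of egg-bearing mothers and their clutches,
   with neckteeth, pedestal and three morphometric traits recorded in
   instars 1 and 2.

Because multiple juveniles come from the same mother, all models carry
per-mother random intercepts, with mothers identified by a unique
clone-by-treatment-by-index identifier (`make_mother_uid()`).

## The bivariate defense-trait model

For juvenile $i$ of mother $m$ with design row $x_i$ (clone, kairomone,
UVR, indicator-coded, interactions up to order two — the three-way
interaction makes the model unidentifiable at this design size and is
excluded from the final models):

$$
\begin{aligned}
\text{neckteeth}_i &\sim \mathrm{Binomial}(5,\ \mathrm{logit}^{-1}(\eta^N_i)),
& \eta^N_i &= x_i^\top\beta^N + u^N_{m(i)},\\
P(\text{pedestal}_i \le k) &= \mathrm{logit}^{-1}(\tau_k - \eta^P_i),
& \eta^P_i &= x_i^\top\beta^P + u^P_{m(i)},
\end{aligned}
$$

with ordered thresholds $\tau_1 < \tau_2$ and independent mother effects
$u^N_m \sim N(0, \sigma_N^2)$, $u^P_m \sim N(0, \sigma_P^2)$. The two
responses share the design but not their random effects (a cross-response
correlation would be a natural extension; the present model treats them as
independent). Following the standard cumulative-logit parameterization the
pedestal predictor has **no separate intercept** — the thresholds are its
intercepts. A separate intercept would lie on an exact likelihood ridge
with them; the reported coefficients are unaffected because all
non-intercept effects are identified as contrasts.

The same model with a single 3-level treatment factor (`control`, `PAR`,
`UVR`; all exposure durations pooled, since duration is not a predictor)
is the effectivity model. The instar-1 and instar-2 defense models have
identical structure and are fitted separately; the biological
interpretation differs (instar-1 neckteeth are canalized, instar-2
neckteeth inducible) but that distinction lives in the report, not the
code path.

## The morphometric model

Body length, body width and spina length (mm) are strongly correlated, so
they are modelled jointly as a zero-truncated trivariate Gaussian:

$$
y_i \sim N_3(B^\top x_i + U_{m(i)},\ \Sigma)\ \big|\ y_i > 0,
$$

with per-trait, per-mother random intercepts and an unstructured residual
covariance $\Sigma$. The design crosses clone, instar, kairomone and UVR up
to three-way interactions (the four-way interaction is excluded for the
same identifiability reason). `truncated_mvn_loglik()` evaluates the exact
truncated density; the positive-orthant probability is computed
deterministically by conditioning and adaptive quadrature
(`mvn_orthant_prob()`, absolute accuracy well below $10^{-6}$). At the
observed trait scales every mean is many residual standard deviations above
zero, so the truncation constant is 1 to within numerical precision; the
sampler therefore runs with the *assume-negligible-truncation* switch,
which makes the model fully conjugate. Records with missing trait
components (lost measurements are a real feature of such data sets)
contribute their marginal sub-vector density in `morpho_loglik()` and are
handled inside the sampler by data augmentation, which is exactly
equivalent.

## Priors

All fixed-effect coefficients and both thresholds get weakly informative
$N(0, 10)$ priors — flat priors cause real convergence problems for these
models — with the threshold prior restricted by $\tau_1<\tau_2$.
Random-effect scales get half-$N(0, 10)$ priors. The residual covariance
gets a weakly informative inverse-Wishart prior ($\nu_0 = 4$, scale
$10^{-3} I$), chosen over a scale/correlation decomposition because it
admits an exact conjugate Gibbs update; at $n$ in the hundreds its
influence on $\Sigma$ is negligible.

## Posterior computation

No gradient-based engine is assumed; the sampler contract is
diagnostics-based and the algorithm is pluggable. Two samplers ship:

* `sample_posterior()` — a deterministic-scan univariate **slice sampler**
  for arbitrary log-densities (used for oracle checks against conjugate
  closed forms, and available for ad-hoc models).
* the model fitters — `fit_defense_model()` runs a compiled blocked scan
  (Rcpp) combining (i) slice updates of the coefficients in a
  **QR-orthogonalized basis** ($\gamma = R\beta$, reported back on the
  $\beta$ scale), which decorrelates treatment-coded columns, (ii)
  center/gap plus a directional slice update for the thresholds, (iii)
  **non-centered** per-mother effects $u = \sigma z$ updated by per-mother
  slice sampling (avoiding the scale funnel), (iv) exact Gaussian Gibbs
  moves along the two likelihood-invariant translation ridges, and (v)
  slice updates of $\log\sigma$. Three internal scans per stored iteration
  make stored draws close to independent at the prescribed chain lengths.
  `fit_morpho_model()` is a conjugate blocked Gibbs sampler (joint Gaussian
  draw of all 45 coefficients, per-mother Gaussian draws, inverse-Wishart
  covariance draws, slice updates for the random-effect scales).

Chain configurations mirror the study: 5 chains × 4,000 iterations with
half warmup (10,000 retained draws) for the effectivity model, 4 × 2,000
with 1,000 warmup (4,000 draws) for the main models; "half warmup" is
implemented as `floor(n/2)`. A `reduced` preset (4 × 500) ships for
continuous testing and simulation studies. Seeding is strict: chain $c$
uses `seed + c - 1`, so a configuration reproduces bit-identical draws.

Convergence is judged by rank-normalized split-$\hat R$ and bulk effective
sample size, implemented from the reference formulas (split chains, normal
scores, Geyer's initial positive/monotone sequence). The reported $\hat R$
is the maximum of the bulk and folded (median-absolute-deviation)
variants. The workflow gate is the one used for model reduction: any
parameter with $\hat R > 1.05$ (strictly) marks the model unidentifiable,
in which case the highest-order interaction is dropped and the model
refitted — the shipped *final* designs are the reduced ones. Converged
final fits are expected to reach $\hat R < 1.01$. A parameter constant
across all draws gets $\hat R = 1$ with a warning rather than `NaN`, so
screening never crashes.

## Inference outputs

Central credible intervals use empirical quantiles with the
linear-interpolation convention (type 7) — worth stating because endpoints
near zero decide "strong effect" calls. An effect is **strong** when its
95% interval excludes zero; an endpoint exactly at zero counts as
including it. Point-null hypotheses are tested with **Savage–Dickey
density ratios**: the Bayes factor of $H_0{:}\ \theta = 0$ against the
unrestricted alternative is the posterior over prior density at zero,
with the posterior density estimated by Gaussian kernel density estimation
with Silverman's bandwidth on the pooled draws (a normal-approximation
fallback exists; both are validated against the conjugate analytic ratio
in the tests, which is the enforceable standard given that the original
hypothesis machinery's kernel is unspecified). For linear contrasts such
as UVR − PAR the implied prior sd is propagated
(`coef_sd * sqrt(sum(w^2))`).

The Tollrian induction score — `min(cap, pedestal% + 10% per tooth)` with
pedestal weights A = 0, B = 30, C = 50 and a 100% cap — is provided as a
descriptive summary only (the weights are configurable; the canonical
values are not printed in every source, so they are configuration, not
constants). The analysis itself deliberately models the two traits
bivariately: the score is interval-censored and typically zero-inflated.

## The synthetic-data generator

The generator is the package's test bed: it emulates the statistical
structure of both experiments so the whole pipeline is testable without
any external download.

* **Design**: 2 clones × kairomone × UVR, 6 mothers per clone-treatment
  cell (study range 5–7), 5–10 offspring per mother (uniform); the
  effectivity trial has 3 treatments × 4 durations × 2 mothers × 5
  offspring = 10 juveniles per cell.
* **Traits** are drawn from the fitted model families themselves
  (binomial/cumulative-logit with instar-specific coefficients; truncated
  trivariate Gaussian morphometrics), with maternal random effects
  ($\sigma = 0.5$ on the logit scale; 0.010–0.015 mm for the
  morphometrics).
* **Calibration** follows the study's printed values and qualitative
  findings: instar-1 body length confined to 0.55–0.80 mm and instar-2 to
  0.75–1.00 mm by rejection (the study reports hard observed ranges);
  per-juvenile UVR mortality before instar 2 of 0.55 ("50% or higher");
  one empty design cell (no instar-1 data for clone P5 under
  +kairomone/+UVR); PAR- and UVR-exposed kairomone suspensions share
  identical parameters (no degradation effect); and effect signs and
  magnitudes that reproduce the reported structure — canalized instar-1
  neckteeth (mostly 1–3), kairomone-only instar-2 neckteeth (2–3 for UNI
  without UVR), strong UVR suppression of the instar-1 pedestal (−2
  logits), weaker in instar 2 (−1.5), and UVR reductions of body length /
  width / spina length of −0.05 / −0.025 / −0.06 mm, sized so that the UVR
  size effect is a *strong* effect at the study's design size, as the
  study reports it to be. An earlier, smaller value (−0.03 mm) failed to
  reproduce that reported strength and was recalibrated; this is a
  calibration to the study's findings, not to any test threshold.
* **Seeding**: each design cell derives an independent substream from the
  master seed via a string hash of the cell label, so adding or removing a
  treatment never shuffles other cells' draws.

What the generator does *not* emulate: exposure-duration effects on
kairomone potency (the study found none, so PAR/UVR cells are exchangeable
by construction), food or lamp physics, overdispersion beyond the binomial,
within-clutch correlation beyond the shared mother effect, or
instar-to-instar correlation of the same juvenile's defense traits
(instar rows share only the mother effect, matching the per-instar
analyses). Passing tests therefore certify the statistical machinery under
the model's own assumptions — not that real *Daphnia* data satisfy them.

## Numerical choices and degenerate inputs

* Orthant probabilities: closed form in 1-D, adaptive quadrature over the
  conditioning variable in 2-D/3-D with $|\rho| \to 1$ handled by the
  degenerate limits; cached per unique mean vector in `morpho_loglik()`.
* Ordinal category probabilities are floored at $10^{-300}$ before logs.
* Slice sampling uses stepping-out with shrinkage; non-finite log-densities
  count as outside the slice; a collapsed bracket returns the current
  point.
* Problem sizes in the test suite: the convergence and recovery checks run
  at the study's design size; the recovery study uses 20 seeded replicates
  with 2 chains × 500 iterations per fit, and simulation-calibration
  checks use up to ~10⁴ juveniles — sizes chosen to make Monte-Carlo error
  small relative to the tolerances being asserted.

## Known limitations

* The defense model's mother effects are independent between responses;
  a correlated version is a contract-compatible extension.
* The morphometric sampler assumes negligible truncation; for trait scales
  near zero the exact truncated likelihood is available but the conjugate
  updates would no longer be exact.
* Savage–Dickey estimates degrade when the posterior at the test point is
  extremely thin; the evidence ratio is then effectively 0 and only its
  order of magnitude is meaningful.
* The effectivity model includes mother random intercepts even though only
  two mothers sit in each cell; they are weakly identified individually
  (the hierarchical scale is what matters) — this mirrors the global
  modelling statement rather than a per-model choice.

## A worked example

```{r example, eval = FALSE}
gen <- generator_config(seed = 1)
juv <- simulate_main_experiment(gen)
fit <- fit_defense_model(juv[juv$instar == 2, ],
                         config = sampler_preset("main", seed = 1))
effect_summary_table(fit)
plot_effect_summary(fit)
```

The pipeline front ends `run_effectivity_analysis()` and
`run_main_analysis()` wrap simulation/ingest, fitting, the identifiability
gate, effect tables, hypothesis tests and forest plots into a reproducible
artifact directory; `make_report()` collates a run into a single markdown
report. A thin command-line wrapper (`inst/cli/uvrdefense-cli.R`) exposes
`simulate` / `fit` / `report` subcommands over the same functions.
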