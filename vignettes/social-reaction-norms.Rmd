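---
title: "Modelling individual plasticity in social network phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling individual plasticity in social network phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In fission–fusion animal societies observed by photo-identification —
cetaceans are the motivating case — repeated boat surveys yield *encounters*:
records of which individuals were seen grouped together. Under the gambit of
the group (all members of an observed group are taken to be associating),
these records aggregate into weighted social networks per time window, and
each individual acquires window-level social phenotypes. The scientific
question `plastnet` addresses is how those phenotypes respond to
environmental variation — a climate-style index and a resource-abundance
count — and, crucially, whether *individuals differ in their response*
(individual-by-environment interaction, I×E), because population-level
predictions built from a single average reaction norm can be badly wrong
when they do.

# The pipeline

## Networks and node traits

Encounters are converted to a group-by-individual matrix per window
(calendar year, or calendar year-month). Edge weights are the simple ratio
index,

$$\mathrm{SRI}_{ij} = \frac{x_{ij}}{n_i + n_j - x_{ij}},$$

with $x_{ij}$ the number of encounters containing both individuals and
$n_i$ the number containing $i$; the index runs from 0 (never together) to
1 (always together). The sampling unit is the encounter, so "seen apart"
means appearing in different encounters; under this convention the
joint-sighting denominator above coincides with the together/apart
formulation of the index.

Three node traits are computed per individual per window:

* **strength** — the sum of incident edge weights; a gregariousness proxy.
* **weighted clustering coefficient** — Barrat's form
  $C_i = \frac{1}{s_i(k_i-1)}\sum_{j,h}\frac{w_{ij}+w_{ih}}{2}a_{ij}a_{ih}a_{jh}$,
  undefined for nodes with fewer than two neighbours. The field's verbal
  definitions rarely pin down the weighted variant; Barrat's is the common
  default in the ecosystem these analyses use, and an Onnela-form
  alternative is exposed behind `method = "onnela"` as a sensitivity
  switch rather than asserted.
* **size-corrected closeness** — with edge lengths $1/w$ (stronger
  association = shorter path), reachable set $R$, $r=|R|$ and $n$ nodes,
  $\left(r/\sum_{j\in R} d_{ij}\right)\cdot\left(r/(n-1)\right)$. On a
  connected graph this is exactly the inverse mean path length; the
  reachable-fraction factor makes disconnected and different-sized
  networks comparable and sends isolates to 0. The reciprocal-weight edge
  length is likewise a convention, chosen because association indices are
  similarities; it is the standard transform for association networks.

Three filters mirror long-term photo-ID practice, all exposed as
parameters with the conventional defaults: encounters of individuals
younger than 3 years are removed (dependent calves express their mother's
associations; unknown birth years are retained since only animals first
seen as calves have known ages); months with fewer than 10 encounters are
dropped (networks from fewer grouping records are unreliable); and an
individual's *own* scores in a window are masked when it has fewer than 5
sightings there — without rebuilding the network, because rarely seen
individuals still shape everyone else's social environment. Individuals of
unknown sex are similarly kept in the networks but flagged out of the
models.

## The random-regression model

For each trait × covariate × timescale cell (12 cells by default) the
model on the transformed trait $y_{it}$ is

$$y_{it} = \beta_0 + \beta_s s_i + \beta_x x_t + \beta_{sx} s_i x_t
  + u_{0i} + u_{1i} x_t + a_{year(t)} + c_{month(t)} + e_{it},$$

with $(u_{0i}, u_{1i}) \sim N(0, G)$ correlated individual intercepts and
slopes, year effects $a$ sharing an AR1 correlation
$\mathrm{corr}(a_s, a_t) = \rho^{|s-t|}$ across all individuals, iid
year-month effects $c$ (monthly models only), and iid residuals. The
covariate is mean-centred and scaled to unit variance over the rows
entering each fit (population-sd convention by default; the sample-sd
convention is a switch — each satisfies "sd = 1" under its own
definition).

Two deliberate modelling choices deserve emphasis:

* **Transformed response rather than link functions.** Right-skewed
  strength and closeness are log-transformed and clustering is
  logit-transformed, then an identity-link Gaussian LMM with *exact*
  marginal likelihood is fitted. Gaussian models with log/logit links and
  random effects would need approximate integration and make nested LRTs
  murkier. The error model consequently lives on the transformed scale;
  validation therefore rests on parameter recovery under the package's own
  generative model, not on matching any particular field estimate.
* **ML, not REML**, throughout, so every likelihood-ratio comparison in
  the testing hierarchy is coherent.

The implementation profiles the fixed effects out by GLS and maximizes
over variance components on an unconstrained scale (log variances, atanh
correlations) with multi-start L-BFGS-B (3 starts by default; deterministic
jitter) and a Nelder–Mead polish when the quasi-Newton run stalls —
mirroring the optimizer-switching these models commonly need. The marginal
covariance is never formed as a dense $n \times n$ matrix: likelihood
evaluations use per-individual Cholesky blocks plus a stabilized Woodbury
correction $M = I + L_D^\top (U^\top B^{-1} U) L_D$ for the year/month
factors, which stays well conditioned as components shrink to the boundary.
Convergence tolerance is `factr = 1e4` (~1e-12 relative on the objective);
a fit with fewer than two distinct covariate values among repeated-measures
individuals fixes the slope components at zero with a warning.

## The testing hierarchy and repeatability

Variance components are tested in the stated order, with an audit log:

1. **Intercept–slope correlation**: full vs correlation-suppressed model,
   $\chi^2_1$ (the correlation is interior). If clear ($p < 0.05$; values
   in $(0.05, 0.07)$ are flagged "marginal"), individual variation in
   plasticity is established and testing stops.
2. **Random slopes**: correlation-suppressed vs intercept-only model. The
   slope variance sits on its boundary under the null, so the reference is
   the 50:50 $\chi^2_0{:}\chi^2_1$ mixture — $p = \tfrac12 P(\chi^2_1 \ge
   2\Delta\ell)$, and $p = 0.5$ at a zero statistic.
3. If the correlation-suppressed model will not converge, the fallback is
   the 2-df comparison of the full vs intercept-only model.

Marginal repeatability follows the variance-partitioning approach for
random-regression models: with a standardized covariate the marginal
among-individual variance is $V_{int} + V_{slope}$ and

$$R = \frac{V_{int} + V_{slope}}
  {V_{int} + V_{slope} + V_{year} + V_{month} + V_{resid}},$$

with the conditional version using $V_{ind}(x) = V_{int} + 2x\,Cov + x^2
V_{slope}$, evaluated at $x \in \{-2,\dots,2\}$ SD by default. Fixed-effect
variance is excluded (marginal sensu the repeatability literature); a
switch drops year/month components from the denominator for sensitivity.

# The synthetic world

Because the motivating field data cannot ship with the package, the
generator produces data *with the statistical structure the analysis
assumes*, sized to a multi-decade dolphin study: 129 individuals, 32 years,
9–35 surveys per year (uniform; mean 22) in May–September, an 84% chance of
photo-identifying each group member, and per-survey availability of 0.5
(roughly half the population uses the core study area in a year). The
environment is either a stationary monthly Gaussian AR1 index
(lag-1 autocorrelation 0.4, marginal SD 1; yearly series = monthly means)
or an overdispersed seasonal count (negative binomial, dispersion 5,
mid-summer Gaussian-bump peak at month 7; yearly series = sums) — the
climate-index and resource-count archetypes.

Sociality is generated mechanistically. Individual $i$ in month $t$ has
latent gregariousness
$\eta_{it} = \beta_0 + \beta_x x_t + \beta_s s_i + \beta_{sx} s_i x_t +
u_{0i} + u_{1i} x_t$ with $(u_{0i}, u_{1i})$ drawn from a 2×2 covariance
(defaults $V_{int} = 0.25$, $V_{slope} = 0.04$, $Cov = -0.06$, i.e. a
correlation of $-0.6$ — social phenotypes in such studies typically show
strongly negative mean–plasticity correlations). Available individuals are
partitioned into groups sequentially: in random order, each joins an
existing group with weight $\exp(\eta_{it}) \times |g| \times a_{ig}$
($a_{ig}$ = community affinity, default ratio 4 across 3 latent
communities) or founds a new group with unit weight. The observed data no
model ever sees directly: each group member is then detected independently
with probability 0.84 and undetected members vanish from the record.

The group-formation rule is the package's own construction — observation
studies record groups but do not model their assembly. It was chosen
because it makes expected group size monotone in $\eta$, so the latent
effect sizes propagate to network strength in the expected direction; a
Monte-Carlo test verifies the monotonicity. What a green test establishes
is therefore that *the pipeline recovers the structure this world
generates* — direction of environmental effects, presence and sign of I×E,
repeatability patterns. Features of real data that this world does not
emulate include spatial/home-range structure, tidal and movement
constraints, demographic turnover within the study period, observation
effort correlated with conditions, and photo-quality heterogeneity.

All randomness descends from one root seed via fixed offsets, so identical
configurations reproduce byte-identical CSVs.

# Numerical and design notes

* Degenerate inputs: empty encounter windows are errors; a network of one
  node gives closeness 0 by convention; clustering is `NA` (not an error)
  below two neighbours; logit/log domain violations are dropped and
  counted, not fatal.
* LRT statistics are clamped at zero (optimizer noise can make a nested
  model score infinitesimally higher).
* The 2-df fallback uses a plain $\chi^2_2$, matching the reported
  practice it mirrors, although a boundary argument could justify a
  mixture there too; it only runs on non-convergence of the
  zero-correlation model.
* Month effects are indexed by year-month label (nested in year, not
  crossed); the AR1 applies to year effects shared across individuals
  rather than to residuals — both are the more natural reading of the
  design this package reimplements, and both are stated here as
  conventions rather than facts about any original software.
* Estimation is unaffected by row order and node labelling; tests assert
  both.

# Known limitations

* The Gaussian-on-transformed-scale error model is not the same
  distribution as a link-function model on the natural scale; coefficients
  are comparable in direction and approximate magnitude, not identical.
* Wald $\chi^2$ fixed-effect tests (profiled GLS SEs) are asymptotic; no
  small-sample (Kenward–Roger-style) correction is attempted under ML.
* The sequential group-formation mechanism is one of many that produce
  monotone group-size responses; inference about real grouping mechanics
  is out of scope.
* Association indices other than the SRI (e.g. half-weight) and
  permutation-based association tests are deliberately not implemented.
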