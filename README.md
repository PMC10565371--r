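# plastnet

Individual plasticity in animal social network phenotypes.

`plastnet` is an R package for behavioural ecologists studying how social
behaviour in fission–fusion societies — bottlenose dolphins are the
archetype — responds to environmental variation, and whether individuals
*differ* in that response. It reimplements, as a tested and reusable
pipeline, the full analysis chain from photo-identification encounter
records to random-regression mixed models:

1. **Networks** — encounters (groups of individuals seen together) become
   per-year or per-month weighted social networks via the gambit of the
   group and the simple ratio association index
   `SRI_ij = x_ij / (n_i + n_j − x_ij)`, with the field's standard
   filters: drop observations of calves younger than 3, drop months with
   fewer than 10 encounters, mask an individual's own scores in windows
   where it was sighted fewer than 5 times (without rebuilding the
   network — rare individuals still shape everyone else's metrics).
2. **Node traits** — strength (gregariousness), Barrat weighted clustering
   coefficient (local cohesion; undefined below two neighbours), and
   size-corrected closeness on reciprocal-weight shortest paths
   (connectedness to the wider population).
3. **Random regression** — on the transformed trait (log for strength and
   closeness, logit for clustering), a Gaussian mixed model fitted by
   exact maximum likelihood:

   `y_it = β0 + βs·sex + βx·x_t + βsx·sex·x_t + u0_i + u1_i·x_t + a_year + c_month + e_it`

   with correlated individual intercepts/slopes `(u0, u1) ~ N(0, G)`,
   AR1-correlated year effects, month effects at the monthly timescale,
   and the covariate mean-centred and scaled to unit variance.
4. **Inference** — type-III Wald χ²(1) tests for fixed effects; the
   two-stage LRT hierarchy for plasticity: first the intercept–slope
   correlation (χ²(1)), then — only if that is unclear — the random
   slopes against the boundary-correct 50:50 χ²₀:χ²₁ mixture, with a 2-df
   fallback when the zero-correlation model will not converge; marginal
   and conditional repeatability
   `R = (V_int + V_slope) / (V_int + V_slope + V_year + V_month + V_resid)`.
5. **Synthetic data** — a generator that emulates a multi-decade boat
   survey (129 individuals, 32 years, 9–35 surveys/year in May–September,
   84% within-group photo-ID probability), driving group formation through
   individual reaction norms on a latent gregariousness scale, so every
   stage is testable without any field data.

## Worked example

Simulate eight years of surveys with a seasonal resource count driving
gregariousness (latent effect 0.5), build monthly networks, and fit the
strength model:

```r
library(plastnet)
cfg <- sim_config(n_individuals = 45, n_years = 8, surveys_per_year = c(48, 52),
                  env_model = "seasonal_count",
                  fixed_effects = c(intercept = 1, environment = 0.5, sex = 0.1),
                  rn_covariance = matrix(c(0.25, -0.06, -0.06, 0.04), 2),
                  seed = 2024)
env <- simulate_environment(cfg)
pop <- simulate_population(cfg)
enc <- simulate_encounters(cfg, env, pop)

enc  <- filter_calves(enc, pop)
wins <- drop_sparse_windows(window_encounters(enc, "month"), 10, verbose = TRUE)
#> drop_sparse_windows: removed 3 of 40 windows (< 10 encounters), leaving 37
nets <- lapply(names(wins), function(w) build_network(wins[[w]], window = w))
tab  <- metrics_table(nets, pop, env, timescale = "month")

d  <- tab[tab$included, ]
yt <- transform_response(d$strength, "log")
d  <- d[attr(yt, "keep"), ]
md <- data.frame(y = as.numeric(yt),
                 x = as.numeric(standardize_covariate(d$covariate_raw)),
                 id = d$individual, sex = d$sex, year = d$year, month = d$month)
f_full <- fit_rrn(md, "full", include_year_ar1 = TRUE, include_month = TRUE, seed = 1)
f_full
#> <rrn_fit> random = full + year AR1 + month | n = 551 obs, 34 individuals | logLik = 102.977
#> fixed effects:
#>   (Intercept)    2.2639 +/- 0.0715
#>   sexM          -0.0012 +/- 0.0189
#>   x              0.1169 +/- 0.0262
#>   sexM:x         0.0112 +/- 0.0175
#> variance components: V_int=0.0007371 V_slope=0.0003878 corr=-1.000
#>   V_year=0.008993 rho=0.731 V_month=0.01594 V_resid=0.03401
```

Months with more of the resource have clearly more gregarious dolphins —
the simulated positive effect comes back positive
(`wald_tests(f_full)` gives χ²(1) = 19.9, p = 8.2e-06 for `x`), while sex
and its interaction are flat, as simulated. The plasticity test hierarchy
then runs in order:

```r
f_zc  <- fit_rrn(md, "zero_corr",      include_year_ar1 = TRUE, include_month = TRUE, seed = 1)
f_int <- fit_rrn(md, "intercept_only", include_year_ar1 = TRUE, include_month = TRUE, seed = 1)
tests <- plasticity_tests(f_full, f_zc, f_int)
cat(tests$procedure, sep = "\n")
#> 1: correlation LRT (full vs zero-corr), stat 3.023, p 0.08208 -> unclear, proceed
#> 2: random-slope boundary LRT (zero-corr vs intercept-only), stat 0.000, p 0.5 -> slopes unclear

marginal_repeatability(f_full)
#> <rrn_repeatability> marginal R = 0.0187
#> conditional R(x):
#>   x = -2 : R = 0.0699
#>   ...
#>   x = +2 : R = 0.0025
```

At this scale the data cannot establish individual variation in plasticity
(both stages unclear), and repeatability is low — with the fitted negative
intercept–slope correlation concentrating what little among-individual
variation there is at *low* resource levels (R = 0.07 at −2 SD vs 0.002 at
+2 SD), the fan-in pattern such studies report.

The whole 3 traits × 2 covariates × 2 timescales grid runs with
`run_study()` (or the CLI: `inst/cli/plastnet all --seed 1 --out results/`),
which writes `fixed_effects.csv`, `variance_components.csv`,
`lrt_decisions.csv`, `repeatability.csv`, a filtering log and a text
report.

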