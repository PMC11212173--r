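# mcpaccess

Multilevel modelling and travel-time accessibility analysis of modern
contraceptive use among women of reproductive age.

## What problem this solves, and for whom

Reproductive-health analysts working with DHS-style women's survey data
routinely need the same pipeline: screen the sample to users of any
contraceptive method who are not currently pregnant, recode the survey
items (modern vs traditional method, media-exposure composite, collapsed
education and wealth, district-level community aggregates), screen
variables with chi-square tests and variance inflation factors, fit a
district random-intercept logistic model and report intraclass
correlation and average marginal effects, measure geographic access to
health facilities over the road network, and map district-level use with
a natural-breaks classification. `mcpaccess` packages each of those
stages as a tested R function, plus a synthetic-data generator emulating
the hierarchical structure of such surveys (the real microdata are
access-restricted), so the whole analysis runs end to end out of the box.

## The model at the core

For woman *i* in district *j*, with π<sub>ij</sub> the probability of
using a modern method:

```
logit(π_ij) = β₀ + β₁x₁ij + … + βₙxₙij + u₀j,   u₀j ~ N(0, σ²ᵤ)
```

The marginal likelihood is maximised with adaptive Gauss–Hermite
quadrature (7 nodes by default) over the random intercept; the
latent-variable intraclass correlation is ICC = σ²ᵤ / (σ²ᵤ + π²/3); model
comparison uses AIC = 2k − 2ℓ and likelihood-ratio tests across the
standard four-model sequence (empty; individual covariates; community
covariates; both). Effects are reported as average marginal effects —
mean changes in population-averaged probability against the reference
category. Accessibility uses driving minutes per road segment,
`length / speed(class) × 60`, with class speeds 120/80/60/40/20 km/h
(primary/secondary/tertiary/residential/tracks), lakes as restrictive
barriers, a 15 km facility snapping tolerance, and six service-time bands
(0–30, 30–45, 45–60, 60–90, 90–180, 180–240 minutes; beyond 240 is
unreachable). District map values are classified with exact
(dynamic-programming) Jenks natural breaks, the lowest of five classes
holding no-data and zero districts.

## Worked example

```r
library(mcpaccess)
cfg <- pipeline_config(synthetic = sim_config(seed = 1))
bundle <- run_pipeline(cfg, outdir = "out")
```

The run logs the screening accounting and stage summaries:

```
simulating 112 districts (seed 1)
screening: 18405 women in, 8187 non-users excluded, 999 pregnant users excluded, 9219 analytic
coded 9219 analytic records; modern share 52.3%
bivariate screening kept 8 of 17 variables (p < 0.05)
model sequence: 4/4 fits converged; lowest AIC: Model 4
facilities: 6 located, 0 unlocated (tolerance 15 km)
Jenks: 5 classes, top bound 1.93%
```

`bundle$models` holds the four fits:

```
    model n_params   loglik      aic sigma_u2   icc
1 Model 1        2 -6325.99 12655.99   0.1053 0.031
2 Model 2       25 -6255.91 12561.82   0.1136 0.033
3 Model 3        8 -6315.24 12646.48   0.0737 0.022
4 Model 4       31 -6245.50 12553.00   0.0813 0.024
Lowest AIC: Model 4
```

Reading: the empty model attributes about 3% of latent outcome variance
to between-district differences (ICC 0.031); adding both individual and
community covariates gives the best AIC, and the residual district
variance drops to 0.081. `bundle$ame` gives marginal effects of the
best covariate model, e.g. (seed 1):

```
                 variable      level     ame     se stars
                education secondary+  0.0441 0.0192    **
                   wealth     middle  0.0583 0.0145   ***
community_facility_access       high -0.0777 0.0169   ***
```

— secondary+ education raises the probability of modern use by about 4.4
percentage points; living in a district with high community facility
access lowers it by about 7.8 points, the direction reported in this
literature. `bundle$access$report` gives per-district travel-time band
shares and median minutes (flagging districts whose median exceeds 240),
and `bundle$classification` the five Jenks classes of each district's
share of modern users.

A thin CLI over the same functions ships in
`inst/scripts/mcpaccess-cli.R` with subcommands `simulate`, `code`,
`describe`, `model`, `access`, `classify`, `all`, and `--config`,
`--seed`, `--outdir` options.

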