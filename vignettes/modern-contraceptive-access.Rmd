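---
title: "Multilevel modelling and travel-time accessibility of modern contraceptive use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel modelling and travel-time accessibility of modern contraceptive use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcpaccess)
```

## The analysis this package implements

`mcpaccess` implements, as reusable and tested components, a complete
analysis of modern-contraceptive utilization of the kind run on DHS-style
women's survey data: screening and recoding of survey records, descriptive
cross-tabulation with chi-square and VIF checks, a random-intercept binary
logistic model for individual and community (district) determinants, a
road-network travel-time analysis of access to health facilities, and a
Jenks natural-breaks district classification of use. Because the microdata
such analyses rely on are access-restricted, the package ships a
synthetic-data generator that emulates their hierarchical structure; every
downstream stage runs end to end on generated data.

## The outcome and the recodes

Among women using any method to prevent pregnancy, the outcome is binary:
modern methods (female and male sterilization, IUD, injectables, implants,
pill, male and female condom, emergency contraception, other modern)
versus traditional methods (rhythm, withdrawal, lactational amenorrhea,
other traditional). The screening flow first excludes women using no
method, then currently pregnant users; `apply_sample_filter()` records the
accounting so input = excluded non-users + excluded pregnant + analytic
holds exactly.

Recodes follow the usual DHS conventions: education collapses secondary
and higher into one `secondary+` category; the five wealth quintiles
collapse to poor/middle/rich; the media composite dichotomises each of
three frequency items (newspaper, radio, television; codes 0/1/2) to
access vs no access, sums them, and classes the 0--3 sum as low (0),
medium (1) or high (2--3).

Community variables aggregate individual characteristics to the district:
share of young women (15--29), share in middle/rich households, share
exposed to family-planning media messages, share with secondary+
education, share who visited a health facility in the last 12 months.
Each district proportion is dichotomised at the *median* of the
district-level distribution, ties going to `high`; this median split is a
design choice — the source convention says only "based on the
distribution" — and it is the same rule the media composite uses, so the
package applies it uniformly and exposes the raw proportions for anyone
wanting a different cut. Whether the family-planning media indicator is
the same three media items or a separate exposure item is not settled
either; the generator carries a distinct `fp_media_message` column and
`aggregate_community()` falls back to "any media exposure" when it is
absent.

## The multilevel model

For woman $i$ in district $j$, with $\pi_{ij}$ the probability of modern
use,

$$\log\frac{\pi_{ij}}{1-\pi_{ij}} = \beta_0 + \beta_1 x_{1ij} + \cdots +
\beta_n x_{nij} + u_{0j}, \qquad u_{0j} \sim N(0, \sigma_u^2).$$

`melogit()` maximises the marginal likelihood, integrating each cluster's
random intercept by **adaptive Gauss--Hermite quadrature**: nodes are
recentred at the cluster's posterior mode and rescaled by the curvature
there, which keeps 7 nodes (the default; configurable) accurate even for
larger $\sigma_u$. Doubling the node count changes the log-likelihood by
less than $10^{-6}$ on typical designs, and the test suite checks the
quadrature against dense trapezoid integration on a single-cluster
fixture. The optimiser is L-BFGS-B on $(\beta, \log\sigma_u)$ with an
analytic score (the adaptive centering is held fixed when
differentiating; the inconsistency this introduces is at the
quadrature-error level and is itself tested against finite differences).
Starting values come from the ordinary logistic fit. Standard errors are
from the inverse observed information (central differences of the score);
the variance CI is formed on the $\log\sigma_u$ scale and back-transformed.
$\log\sigma_u$ is bounded below at $\log 10^{-5}$, so a fit on unclustered
data reports a variance of effectively zero rather than diverging.

The model sequence mirrors the standard four-model presentation: empty
model, individual covariates, community covariates, both; each reports
$\sigma_u^2$, the latent-variable ICC
$\sigma_u^2/(\sigma_u^2 + \pi^2/3)$, log-likelihood and AIC
($2k - 2\ell$, audited exactly), and the sequence selects the lowest-AIC
model. A Wald chi-square over all non-intercept fixed effects is reported
per model. Nested models are compared with `likelihood_ratio_test()`.

Effects are communicated as **average marginal effects**: for each
non-reference category, the mean over all women of the difference in
population-averaged probability (integrating the random intercept over
its prior) between that category and the reference, with delta-method
standard errors and significance stars at the 1/5/10% levels. Under
$\sigma_u \to 0$ with a single binary covariate this reduces to the plain
difference of logistic probabilities, which the tests verify in closed
form.

## What the generator emulates — and what it does not

`simulate_women()` draws districts, district intercepts
$u_j \sim N(0, \sigma_u^2)$, covariates from configurable margins
(defaults follow the background-characteristics table of a 9,238-woman
users sample), and the outcome from the inverse-logit linear predictor.
Defaults that matter:

* **Effect sizes** (`default_betas()`): nonzero only for marital status,
  household-head sex, pregnancy termination, education, wealth, religion
  and the facility-visit indicator — the covariates reported as
  associated with method choice — with signs matching the reported
  marginal effects and magnitudes of roughly four times the
  probability-scale effects.
* **Intercept calibration**: the intercept is solved deterministically
  (exact convolution of the discrete covariate contribution, Gauss--Hermite
  over $u$, `uniroot`) so the marginal modern share among users is 53.2%,
  the published figure.
* **Clustered community attributes**: residence and facility-visit
  propensity are drawn at the district level (districts are predominantly
  urban or rural; facility access is a logit-normal district propensity
  with sd 0.5 on the log-odds scale). Independent per-woman draws would
  make the district median splits pure noise — majority residence would
  even be constant. A contextual effect
  (`default_community_betas()`: high community facility access, $-0.35$
  log-odds) implements the community-level term of the model; with it the
  default-design sequence selects the combined model by AIC, the
  qualitative result reported for the real data.
* **Sampling design**: 112 districts, 60--270 women each (mean ≈ 165),
  use-of-any-method probability 0.5566 and pregnancy probability 0.1034,
  so the screened analytic sample lands near the published 9,238.
* All other covariates are drawn independently per woman; no
  covariate--covariate correlation is simulated unless configured. One
  master seed drives deterministic per-stage child seeds
  (`derive_seed()`), so any stage can be rerun in isolation.

What passing tests on these data do **not** show: robustness to informative
sampling weights, item missingness, correlated covariates, or
mis-specified random-effect distributions — none of which the generator
produces. Results on real survey data depend on those features.

## The accessibility model

Travel time along a road segment is `length / speed(class) * 60` minutes,
with class speeds primary 120, secondary 80, tertiary 60, residential 40
and tracks 20 km/h (a 60 km tertiary stretch is 60 minutes; 60 km of
tracks is 180). The source convention also lists one fixed assigned time
per class; the package computes the length-dependent time per edge, which
is what a routing analysis needs, and the fixed per-class numbers are
recovered exactly at the listed lengths.

`build_road_graph()` merges shared segment endpoints into nodes (1 mm
coordinate epsilon), weights each edge by its driving minutes, and
collapses parallel edges to the cheaper one. Lakes are **restrictive
barriers**: `apply_barriers()` removes every edge whose geometry passes
through a lake polygon, so routes divert (or districts become
unreachable); removal can only lengthen travel times, which is tested as
a monotonicity property. Facilities snap to the nearest point on the
nearest edge within a 15 km search tolerance, splitting the edge at the
projection — snapping to the nearest existing node instead would distort
times on coarse rural segments. Facilities beyond tolerance are reported
as unlocated and excluded from routing, mirroring the real analysis'
accounting of facilities that failed to locate on the network.

`travel_time_surface()` computes every node's minimum driving time
towards the nearest facility (roads are undirected with symmetric speeds,
so "towards the facility" equals the reverse direction) and assigns the
six non-overlapping service bands $(0,30], (30,45], (45,60], (60,90],
(90,180], (180,240]$ minutes, band 1 including 0; beyond 240 minutes or
disconnected is *unreachable*. Women (at their district centroids by
default, since real coordinates are displaced anyway) are mapped to their
nearest node; the district report gives band shares, the median minutes
and a flag when the median exceeds 240 — the "more than four hours"
situation.

The toy geography is a planar km grid (no geodesy — only lengths and
speeds enter the model), with classed roads, facilities on the network
(a configurable fraction deliberately off it), rectangular lakes placed
over interior grid cells, and a rectangular district partition. All
layers export deterministically to GeoJSON.

## District classification

`jenks_breaks()` is an exact dynamic program minimising total
within-class sum of squared deviations; ties prefer smaller upper bounds,
and the cost is verified against brute-force enumeration for small
inputs. `classify_districts()` uses five classes with the lowest class
holding no-data *and* true-zero districts (the "smallest class at 0"
convention is read as absorbing both), the remaining positive values
Jenks-classified above it with the top bound at the data maximum; with
fewer distinct positive values than classes the classification is
top-aligned. The goodness-of-variance fit is reported for transparency.
The value classified is each district's share of all modern users (in
percent): a national map whose largest district holds a few percent is
only consistent with that denominator, not with within-district
prevalence.

## Numerical and degenerate-input choices

* Bernoulli log-likelihoods use `plogis(·, log.p = TRUE)`; linear
  predictors are clamped at ±35 before exponentiation, so no evaluation
  returns NaN.
* Exact collinearity in the VIF screen yields an infinite, flagged VIF —
  a sentinel, not an exception; rank-deficient model designs raise an
  explicit error naming the aliased terms.
* Chi-square tests use no continuity correction by default (a `yates`
  flag exists for 2×2 tables); tables with a zero expected cell raise a
  degenerate-table error.
* Cross-tabulations print percent-of-grand-total by convention (the two
  outcome columns of a category sum to the category's share), with a row
  percent option.
* The cluster column is configurable (`cluster` argument throughout):
  analyses of this type sometimes model PSUs and sometimes districts, and
  the package does not hard-wire either.

## Problem sizes used in the shipped checks

The test suite fits the recovery study at 200 districts × 50 women
(σ²ᵤ = 0.10, 100 replicates) and the LR-calibration study at 100
districts × 20 women (500 replicates); the acceptance script runs the
full pipeline at the default design (112 districts, mean 165 women). These
sizes give Monte-Carlo standard errors small enough for 3-SE recovery
checks and a binomial ±1% on the rejection rate.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(synthetic = sim_config(seed = 1))
bundle <- run_pipeline(cfg, outdir = "out")
bundle$models$comparison   # four fits, ICC, AIC, lowest-AIC selection
bundle$ame                 # marginal effects of the best covariate model
bundle$access$report       # district band shares and median minutes
bundle$classification      # Jenks classes of district map values
```

## Known limitations

Sampling weights are not implemented (the analysis this mirrors did not
describe using them). The model has one random level; woman/PSU/district
three-level designs are out of scope. Band polygons are attribute output
(per-node and per-district labels), not cartography. The Jenks DP is
O(kn²), fine for hundreds of districts, not for rasters.
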