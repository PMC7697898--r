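---
title: "Methods: cluster-based source apportionment of hourly air quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cluster-based source apportionment of hourly air quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, parameters, numerical choices and
limitations of `sourceclust`. It states no empirical result beyond what
the package's tests and `scripts/acceptance.R` compute.

## 1. The polar cluster model

Each retained hour is the vector $[u, v, c]$: with $\theta$ the wind
direction (the direction the wind blows *from*, mapped onto compass
bearings, $x$ east and $y$ north),

$$u = r \sin\theta, \qquad v = r \cos\theta,$$

where the radial variable $r$ is wind speed (m/s) or, optionally,
temperature shifted by its series minimum so $r \ge 0$; $c$ is the
target pollutant concentration. The three coordinates have incompatible
scales, so each is standardized to mean 0 and **sample** standard
deviation 1 before clustering (population vs sample sd is not
distinguishable from practice; sample sd is used and the transform is
stored for inverse mapping). Clustering is plain Lloyd k-means on the
raw standardized triplets — no surface smoothing is applied first.

The clustering outcome is invariant to any fixed rotation or reflection
of the $(u, v)$ plane, so the compass convention only affects reporting.

**Temperature radial.** At sites where a calm-condition source (wood
smoke under stable, cold nights) overlaps traffic at low wind speeds,
wind speed fails to separate them. Temperature does: the wood-smoke
signal concentrates at the lowest temperatures, where meandering winds
sample all directions, producing a "central cluster" that encloses the
origin. Wind direction is kept as the angle in this mode (direction
still resolves the other sources); the radial shift by the series
minimum is an interpretation choice — only the ordering of temperatures
matters to the geometry.

**Calm winds** (below ~0.5 m/s) keep their reported direction; no calm
sector is carved out, because near-origin points are nearly coincident
for k-means regardless of their angle.

### Contributions

The contribution of cluster $k$ at hour $t$ is defined as the observed
concentration if $t$ is assigned to $k$, else 0. This additive
convention makes cluster contributions sum *exactly* to the observed
concentration at every retained hour, and period means of clusters sum
to the period mean concentration — the property that lets monthly and
weekly tables be compared against receptor-model totals. The cost is
that a cluster's "contribution" is really *total ambient concentration
during that cluster's hours*: whatever other sources are active then is
attributed to the cluster. The analysis scripts therefore report the
ground-truth source mix of each cluster, and users should read cluster
contributions as regime totals, not pure source masses.

### Numerical contract of the k-means engine

* Restarts: 20 by default, each initialised by k-means++ ($D^2$)
  seeding from the run seed; best final inertia wins, first winner kept
  on ties, so results are bit-reproducible for a fixed seed.
* Tiny inputs (≤ 12 points and ≤ 250 point-subsets): every distinct
  $k$-subset of data points is additionally tried as an initialisation,
  which in testing always attains the exhaustive-partition optimum.
* Nearest-centroid ties break to the lowest cluster index.
* An emptied cluster is reseeded with the point farthest from its own
  centroid.
* Convergence: assignment fixed point, or 300 Lloyd sweeps.
* Labels are renumbered in decreasing order of mean concentration, so
  cluster 1 is always the dirtiest and output is invariant to restart
  order.
* `sweep_k()` additionally seeds each $k$ from the previous best
  solution's centroids plus the farthest point, which forces inertia to
  be nonincreasing in $k$; consecutive-solution agreement is reported
  as an adjusted Rand index.

**Choosing k is a user decision.** The sweep reports the inertia elbow,
assignment stability and central-cluster emergence, but the package
never auto-selects $k$: the receptor-model context (which sources are
known to exist) is exactly the external information that should drive
that choice.

## 2. The identification rule set

Every rule clause is a named, thresholded predicate; all thresholds
live in `default_rule_config()` and are overridable. The only cut-point
fixed by receptor-modelling practice is the fine/coarse combustion
divider of 0.7; everything else is a declared implementation default.

| Archetype | Clauses (defaults) |
|---|---|
| rwb | upper edge ratio ≥ 0.7; cold/warm ratio ≥ 2; hull contains origin **and** sector coverage ≥ 0.75; temperature slope < 0; a top-2 diurnal hour in {22, 23, 0, 1} |
| traffic | weekend/weekday ≤ 0.85; top-2 diurnal hours hit **both** the morning (6–10) and evening (17–21) windows; wind-speed slope < 0; lower edge ratio ≤ 0.3 |
| industrial | wind-speed slope > 0; ≤ 6 of 16 sectors occupied; SO₂ enrichment ≥ 1.5 (weight 2); weekend ratio in [0.9, 1.1] |
| aeolian | ≤ 10% of contribution below 4 m/s; wind-speed slope > 0; upper edge ratio < 0.7 |
| regional | ≤ 6 of 16 sectors; weekend ratio in [0.9, 1.1]; SO₂ enrichment ≥ 1 with cold/warm SO₂ ratio in [0.5, 2]; NO₂/NOx ≥ 0.5 |

Design notes, in the order they mattered:

* **Edge lines as ratio quantiles.** The upper/lower "limiting edge
  lines" of a PM2.5-vs-PM10 scatter are estimated as the 0.95/0.05
  quantiles of the per-hour ratio (PM10 ≥ 5 µg/m³, ≥ 30 pairs), not as
  regressions through the origin: quantiles are monotone, robust, and
  read directly as end-member fine/coarse ratios.
* **Both rush windows.** A cluster peaking only in the late afternoon
  (wind-driven dust rides the diurnal wind maximum) must not pass as
  traffic; genuine traffic shows morning *and* evening maxima.
* **SO₂ as enrichment, with double weight for industrial.** Raw gas
  shares scale with cluster size, so clauses use share-of-gas divided
  by share-of-hours. SO₂ is the defining industrial tracer; without
  the double weight, wind-blown dust (ws-positive, confined, steady)
  scores as high as industry it cannot be.
* **Central-cluster geometry.** Coverage counts the 16 compass sectors
  holding ≥ 2% of the cluster's below-median-radius points (stray
  single points do not inflate coverage), and the convex-hull origin
  test requires ≥ 3 non-collinear points (otherwise flagged, not
  scored).
* **Scores and the floor.** An archetype's score is the weighted
  fraction of its *evaluable* clauses that fired; unavailable
  diagnostics (too few pairs, zero variance, missing gas) drop out of
  numerator and denominator, lowering confidence without crashing. A
  cluster is labeled `unidentified` when fewer than 2 clauses fired for
  the top archetype or the top score is tied. Small intermittent
  clusters (tens of hours) typically end up unidentified because the
  met-dependence and edge diagnostics require ≥ 30 paired hours — this
  mirrors the known difficulty of both CA and RM with small,
  intermittent sources, and is intended behaviour.
* **Cold/warm months** are the 4 coldest and 4 warmest calendar months
  of the input's own temperature climatology, making seasonality rules
  hemisphere-agnostic.
* **Relative humidity.** The wood-smoke RH tendency ("increases at
  higher RH") has no magnitude anchor in practice; the RH slope is
  computed and reported but excluded from default scoring.

## 3. Receptor models

Both models solve the speciated mass balance $X_{ij} = \sum_k g_{ik}
f_{kj} + e_{ij}$.

**CMB (effective variance).** With profiles $F$ known, each sample is
solved by iterated weighted least squares with effective variance
$V_j = \sigma_j^2 + \sum_k g_k^2 \sigma_{f,kj}^2$; convergence when the
maximum relative change in $g$ falls below $10^{-6}$ (or 100 passes,
then flagged). Zero profile uncertainty reduces to a single weighted
solve, whose standard errors come from the weighted normal-equations
covariance — these are exact for known weights, which Monte-Carlo
checks in the test suite confirm. Contributions are *not*
sign-constrained (classic CMB); negatives are reported with a warning.
Collinear profiles are rejected by name; missing species values are an
error (CMB has no principled down-weighting).

**PMF (uncertainty-weighted non-negative factorization).** Minimises
$Q = \sum_{ij} [(X_{ij} - \sum_k g_{ik} f_{kj}) / \sigma_{ij}]^2$
subject to $G, F \ge 0$ by alternating exact weighted non-negative
least squares (hand-written Lawson–Hanson active set) over rows of $G$
and columns of $F$. Because each block is solved exactly, $Q$ is
nonincreasing by construction; an increase beyond $10^{-8}$ relative
aborts as an internal error. Ten seeded random restarts by default;
convergence at relative $Q$ change ≤ $10^{-9}$ or 500 outer
iterations. The factorization is scale-ambiguous, so profile rows are
normalised to sum to 1 with the scale absorbed into $G$; it is also
rotationally ambiguous, so recovered profiles are compared to truth
*after* best-correlation matching, and per-sample standard errors are
not reported (the objective does not identify them). Missing entries
are down-weighted via $\sigma = 10^6$ and counted. Expected degrees of
freedom are $nm - p(n + m)$; a correctly specified fit should give
$Q/\mathrm{dof}$ near 1.

## 4. CA–RM fusion and error propagation

Clusters sharing a label are summed into per-source hourly series
(additivity is preserved exactly). Period means over a sampling
schedule use only the scheduled hours — the same five weekdays per week
as a filter campaign, for example — with standard error
$\mathrm{sd}/\sqrt{n}$ over those hours. Hours are treated as
exchangeable: autocorrelation of hourly concentrations is ignored, so
these standard errors are somewhat optimistic; this is a documented
limitation, not an oversight. Standard errors of sums and of footer
averages combine in quadrature. Comparison tables flag agreement where
$|CA - RM| \le 2\sqrt{SE_{CA}^2 + SE_{RM}^2}$, and printed values round
half away from zero to one decimal, matching the reporting convention
of the bundled reference tables.

## 5. The synthetic scenario generator

The generator is a statistical emulator of the qualitative source
mechanisms, not a dispersion model: no plume rise, chemistry or
advection. Its calendar is naive local hourly time starting Monday
2018-01-01 (no DST), so weekday logic is unambiguous.

* **Meteorology**: seasonal + diurnal cosine temperature (coldest
  mid-way through the configured coldest month, daily minimum at
  02:00, maximum at 14:00) with Gaussian noise; wind from a mixture of
  regimes (direction-Normal, speed-Weibull) gated by hour and month;
  RH as an anti-phased diurnal cycle clipped to [2, 100]%.
* **Traffic**: rush-hour diurnal profile, weekend factor, ventilation
  dilution $1/(1 + a\,ws)$, and a per-hour exhaust/road-dust
  fine-coarse Beta mixture (`fcr_range`) whose mean preserves the
  configured PM2.5/PM10 ratio — a fixed ratio cannot produce the
  two-edge scatter the traffic rule looks for.
* **Wood burning**: heating-degree driver
  $\max(0, T_{thr} - T)$ (defaults: threshold 12–15 °C, preset
  sensitivity 2.8 µg/m³ per °C), near-midnight diurnal profile, mild
  weekend decrease, low-wind amplification, emitted at any wind
  direction.
* **Aeolian dust**: $b\,(ws - ws_{thr})_+^e$, zero below threshold,
  coarse-dominated.
* **Industrial**: nonzero only in the stack sector at wind speeds
  above activation, increasing with wind speed (fumigation).
* **Noise**: multiplicative, Gaussian in log space truncated at ±4 sd
  and mean-corrected, so factors have mean 1 and coefficient of
  variation exactly as configured and concentrations stay positive.
  PM2.5 is clipped to PM10 after noise with clips counted.
* **Day-to-day variability**: a seeded day-level lognormal factor
  (sd 0.1 in log space) on the human-driven sources.

The two presets encode the study conditions used throughout the tests:
a wood-smoke city (two years, temperature radial, $k = 3$; wood smoke
concentrated at the coldest hours, two traffic wind corridors, calm
meandering nights ending before dawn) and a desert city (two years,
wind-speed radial, $k = 5$; three traffic regimes, dust above 5 m/s
under two high-wind regimes, strongly ventilated traffic). Emission
magnitudes were fixed once, to reproduce the qualitative source
orderings of the corresponding real case studies, before the acceptance
suite was frozen.

**What passing tests show — and don't.** Recovery of the generator's
own labels demonstrates the pipeline end to end under mechanisms the
rules were designed for, with independent noise and clean regime
structure. Real data add instrument artifacts and drift, autocorrelated
meteorology, secondary aerosol formation, and sources outside the five
archetypes; success on the synthetic scenarios is necessary, not
sufficient, evidence for a real site.

## 6. Problem sizes and runtime choices

Simulations in the tests and acceptance script use two simulated years
(17,520 hours) for scenario recovery, 50-sample × 4-species CMB
simulations (five replicates, 5% noise), and 60 × 8 PMF fits — sizes at
which every statistical check is stable while the full suite runs in
about a minute. The CMB "within two standard errors" check is itself a
~95%-probability event per simulation, so it is asserted over five
replicates (≥ 4 of 5), with the 5% bias bound required in each.

## 7. Known limitations

* Cluster contributions are regime totals (see §1); minor sources
  co-occurring with a dominant one are absorbed into its cluster.
* Period standard errors ignore autocorrelation.
* The rule set is deterministic, not probabilistic; confidence is a
  clause count, not a posterior.
* PMF reports no per-sample uncertainties and inherits the usual
  rotational ambiguity of bilinear models.
* Units pass through unchanged; there is no ppm/ppb ↔ µg/m³
  conversion.
* Gaps and screening set cells missing rather than imputing; hours with
  missing wind direction, radial variable or concentration are simply
  excluded from clustering.
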