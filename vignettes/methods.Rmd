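---
title: "Methods: exposure, standardized trends, hotspots and fatality risk for bicyclist collisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposure, standardized trends, hotspots and fatality risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cyclesafe` implements a city-scale surveillance pipeline for bicyclist
road injuries: exposure denominators estimated from weighted
origin–destination travel surveys, standardized fatal and nonfatal
collision-rate trends, spatial hotspot detection for fatal events, and a
binomial generalized additive mixed model (GAMM) of the probability that
a collision is fatal. Because real collision registries and travel
surveys of this kind are administrative data that cannot be
redistributed, the package ships a synthetic-city generator with stored
ground truth; every stage is exercised and validated end to end against
that truth. This vignette records the models, the design choices that
were genuinely open, and what the synthetic validation does and does not
establish.

## The synthetic city and its ground truth

`generate_city()` tessellates a rectangular window (default 20 × 20 km)
into planning zones — Voronoi cells of uniformly seeded points by
default, a rectangular grid on request — and overlays a connected
lattice road network whose edges carry street attributes (lanes, lane
width, speed limit, bike path, transit route). One hundred zones over
400 km² mimics the granularity of a large Latin-American city's planning
zones.

`make_ground_truth()` fixes everything the estimators are later judged
against:

* **Population.** A total commuter-bicyclist population follows a growth
  trend; the default scenario triples between 2011 and 2017 (annual
  factor $3^{1/6}$ from 10,000 in 2011), the kind of growth a decade of
  cycling promotion can produce. It is spread across zones by a
  mildly heterogeneous residence weight (area × lognormal, SD 0.2) and
  across sex (75% male) and quinquennial age bands (gamma-shaped, mode
  in the late twenties).
* **Travel.** Origin–destination flows follow a gravity rule (origin by
  residence weight, destination by weight × exponential distance decay,
  5 km scale). Each flow is routed over the network by shortest path and
  split across zone polygons, giving the true per-zone daily kilometers
  traveled (VKmT) for every year.
* **Risk.** Fatality of a collision follows a logistic model with linear
  vehicle-type contrasts (cargo +2.0, bus +1.0, motorcycle −0.8, …
  against an automobile baseline), infrastructure flags, and three
  smooth effects: a hinge in terrain slope rising after a 3% grade, a
  night-peaked circadian curve, and a hinge in age after 40. The
  intercept is centered by a fixed internal Monte-Carlo draw so the
  marginal fatality fraction is 0.036 — the class imbalance typical of
  urban collision registries (roughly 350 fatal events among 10,000
  collisions over seven years).
* **Hotspots.** Three planted centers multiply the fatality *odds* by 10
  within 1200 m. Centers are planted in the top quartile of zones by
  exposure density (kilometers traveled per unit area): a hotspot in a
  place where nobody cycles produces no fatal events and is not a
  hotspot in any observable sense, and with an area-based quadrat rate a
  weak peripheral cluster is dominated by the downtown background that
  exposure alone produces. These defaults make each planted cluster
  contribute on the order of 30+ fatal events at registry scale — the
  regime the recovery property addresses — so a detector *should* find
  them; the recovery checks then measure whether ours does.

Collision events are placed by sampling a zone proportional to its true
VKmT and a point uniformly within the zone. An alternative placement
(`placement = "od_path"`) samples an OD trip and a point uniformly along
its shortest path; we did not make it the default because a uniform-OD
path process is strongly center-heavy, which makes the no-hotspot
pattern far from spatially homogeneous and entangles every spatial
diagnostic with routing geometry. Zone-proportional placement preserves
exactly the property the rate standardization assumes — spatial
intensity proportional to exposure.

A consequence worth stating: even with no planted hotspots the fatal
pattern is an exposure-driven inhomogeneous process, not complete
spatial randomness (CSR), so a CSR test on it rejects more than 5% of
the time *by design* — this mirrors the real-data argument for using
area-based quadrat rates in the first place. The generator's null
property is therefore tested conditionally: with multiplier 1 the fatal
subset must be an unbiased random thinning of all collisions, which we
verify by comparing its quadrat statistic against random same-size
thinnings.

All generators are deterministic given their seed; child seeds for
internal streams are derived arithmetically and stay below $2^{31}$.

## Exposure denominators

Bicyclist population per zone, survey year, and sex × quinquennial age
stratum is the Horvitz–Thompson expansion $\hat N = \sum_i w_i$ over
bicyclist person records. With the generator's binomial sampling design
(inclusion probability $f$, weight $1/f$) the design standard error is
$\sqrt{N(1-f)/f}$, which the tests use for 3-SE checks.

Daily VKmT expands weighted trip records into OD flows, routes each flow
by shortest network path between zone centroids snapped to their nearest
nodes (no within-zone randomization of endpoints), splits the path at
zone-polygon boundaries, and accumulates in-zone kilometers × daily
trips. Splitting is exact: each segment is cut at every
boundary-crossing parameter and each piece assigned by its midpoint, so
per-zone lengths sum to the path length to float precision. A point on a
shared boundary belongs to the lexicographically smallest zone id — an
arbitrary but deterministic tie-break. Among tied shortest paths the
lexicographically smallest node sequence is returned, again for
determinism.

Years without a survey are filled by stratified linear interpolation
between adjacent observed years and linear extrapolation from the two
nearest observed years beyond them; extrapolations are clipped at zero
because populations and kilometers cannot be negative. Validation errors
compare estimated against actual totals: the total percent error
$100\,|\Sigma a - \Sigma e|/\Sigma a$ and the unweighted mean of
per-stratum absolute percent errors, with zero-denominator strata
excluded and counted explicitly.

## Standardized trends

Monthly fatal and nonfatal rates are directly standardized. By
population: age-stratum rates weighted by the WHO World Standard
Population (the printed quinquennial percentages sum to 100.03, so they
are renormalized to sum exactly to one), scaled to events per 100,000
bicyclists. Weights are renormalized over strata with a positive
denominator, so a rate common to all strata passes through unchanged; a
stratum with events but no denominator makes the cell undefined (NA)
rather than silently zero. By travel: events per 100 million VKmT, with
the month's denominator equal to daily VKmT × days in month.

Yearly summaries are the mean of the 12 monthly rates with a t-based 95%
interval (df = 11; whether t or normal quantiles were intended is
genuinely open — t is the conservative choice and the difference is
negligible at df 11). Undefined months are excluded from the mean and
reported. Between-year change is $100(\bar r_a - \bar r_b)/\bar r_a$
with a Welch t test on the 12 + 12 monthly rates; the sex difference of
the change is the year × sex interaction of a linear model on the
monthly rates. Both choices are ours — the underlying report format
gives p-values without naming tests — and both hold their nominal size
in null simulations.

Indirect standardization divides observed monthly fatal counts by the
count expected if reference age- and sex-specific death rates applied to
the study population. The reference defaults to the pooled all-years
internal rates (per person-month), which makes the study population's
overall SMR against itself exactly 1 — a useful identity — and is
configurable to an external table when one exists.

## Hotspot detection

Ripley's K uses the translation edge correction for rectangular windows
($e_{ij} = |W|/((a-|dx|)(b-|dy|))$), with an uncorrected option for toy
patterns, and pointwise 2.5–97.5% Monte-Carlo envelopes from uniform
simulations with the same n and window.

The kernel surface is the fixed-bandwidth isotropic Gaussian mixture
$f(u) = n^{-1}\sum_i N(u;\,x_i,\sigma^2 I)$ on a regular raster. The
bandwidth maximizes the leave-one-out log-likelihood
$\sum_i \log f_{-i}(x_i)$ over a log-spaced grid from 10 m to 5 km
(the lower bound prevents the coincident-point degeneracy, where the
likelihood diverges as $\sigma \to 0$), followed by one golden-section
refinement between the best candidate's neighbors; ties prefer the
smaller bandwidth.

The 95% highest-density region (HDR) keeps the smallest set of raster
cells holding 95% of the surface mass; its 4-connected components are
extracted by flood fill. The quadrat grid side is the kernel's
significant-cluster scale: the 95% contour of one isolated kernel
cluster is a disk of radius
$\sigma\sqrt{2\ln(1/(1-0.95))} \approx 2.45\sigma$, and a quadrat of
that side lets a cluster span a few quadrats with a clear peak. Rules
that read the side off the HDR components themselves were rejected:
with a dense background the 95% region is one connected blob (no
cluster-scale component exists), and a single-cell island collapses the
grid. The side is rounded so equal rectangles tile the window exactly
(clipped edge slivers would otherwise dominate the count-per-area
ranking), with between 5 × 5 and 32 × 32 quadrats. The mapping from
"95% contour" to a grid size is the least pinned-down step of the whole
pipeline; the side can always be passed explicitly.

The dispersion test is the chi-square index of dispersion
$X^2 = \sum_i (n_i - E_i)^2/E_i$ with expectations proportional to
quadrat area (df = quadrats − 1, upper tail); membership uses half-open
rectangles with the last row/column closed, so counts are an exact
partition. High-risk areas are the quadrats at or above the 95th
percentile of the fatal-event rate per km², ties included, sorted by
rate.

## Fatality-risk model

Covariate screening keeps candidates with bivariate p < 0.2 (chi-square
for categorical, Wilcoxon rank-sum for continuous — the exact bivariate
tests are unnamed in the source analyses; these are the conventional
choices), missingness < 10%, and no pairwise |r| ≥ 0.8 (the more-missing
member of a collinear pair is dropped). Every exclusion is logged with
its failing rule.

The model is a binomial GAMM with logit link: unpenalized linear terms
(vehicle type with automobile baseline, weekday with Sunday baseline,
sex, infrastructure flags), low-rank thin-plate regression splines
(basis dimension 10) for continuous covariates, a cyclic spline for time
of day (the night effect spans midnight, so 24 h wraps to 0), a 2-D
thin-plate smooth of the event coordinates (basis 30) for residual
spatial correlation, and Gaussian random intercepts for zone and year
nested in zone. Smoothing and variance parameters are selected by
restricted likelihood — fast REML (`mgcv::bam`) for n ≥ 4000, REML
(`mgcv::gam`) otherwise. mgcv is the natural engine here; the package's
contribution is the screening, balancing, stratification and
threshold-extraction layers around the fit, each tested against
closed-form oracles (the intercept-only fit must equal the logit of the
prevalence exactly; a single binary covariate must match the 2 × 2
log-odds ratio to 1e-6).

Class imbalance (≈3.6% fatal) is addressed by random oversampling of the
fatal class to a 30% target as a sensitivity analysis: fatal rows are
resampled with replacement until the positive fraction first reaches the
target, which is exact whenever the counts divide. Under this
case-control-style resampling only the intercept changes in expectation;
the slope consistency is checked by simulation.

Coefficients whose magnitude and standard error both explode are flagged
as separation artifacts (a handful of events in one cell of a
categorical cross-tab) rather than reported as finite estimates.

Smooth significance thresholds are the covariate values where the 95%
band of the centered smooth crosses zero, found by linear interpolation
on a 100-point evaluation grid. Because mgcv smooths are centered, the
band crossing estimates where the effect departs from its *average*, so
for a hinge effect the detected threshold sits at the hinge plus a small
offset that shrinks with the mass of the covariate distribution above
the hinge; with a right-skewed slope distribution the detected threshold
lands within a few grid steps of the planted hinge, which is what the
recovery test asserts.

## Problem sizes, tolerances and limits

The validation suite runs the full-scale city (100 zones, 9950 events)
where the claim being checked is about the default study conditions —
hotspot recovery across 50 seeds, the 3.6% fatality calibration — and a
25-zone, 10 × 10 km city elsewhere; these sizes give each check clear
signal while keeping a complete run in minutes. Calibration checks use
500 CSR replicates (dispersion test), 1000 null replicates (year
comparison), and 50 seeds × n = 10,000 (coefficient recovery). Numeric
tolerances follow the quantity: 1e-12 for oracle equivalence of pure
arithmetic (KDE summation, pair counts), 1e-6 for fitted likelihood
optima, 3 design or binomial SEs for stochastic totals.

What passing does not show: the synthetic city has no geocoding error,
no duplicate or missing records (the reader quarantines rather than
imputes), covariates measured without error, stationary covariate
distributions across years, and hotspots that are disks with a constant
odds boost. Real registries violate all of these; results on the
synthetic city validate the estimators' correctness, not the
transportability of any particular effect estimate. Network-constrained
kernels, space–time scan statistics and causal adjustment are out of
scope.
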