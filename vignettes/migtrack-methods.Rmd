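---
title: "Methods: from GPS fixes to breeding outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from GPS fixes to breeding outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(migtrack)
```

migtrack turns raw spring-migration telemetry of Arctic-nesting geese into
a chain of derived products: quality-controlled tracks, migratory
flight/stopover segmentations, utilization distributions, per-individual
migration characteristics, breeding classifications, and comparative
statistics. This vignette explains the models behind each stage, the
tunable parameters and their defaults, the numerical choices, and what the
synthetic-track generator does and does not emulate.

## Track preparation

Fixes arrive as Movebank-style CSV (one row per GPS fix, nominally every
30 minutes; 15-minute devices are thinned). Preparation is deliberately
conservative:

* **HDOP filter.** Fixes with measured horizontal dilution of precision
  strictly above 5 are dropped; fixes without an HDOP value are retained.
  The threshold is dimensionless and standard for waterfowl GPS units.
* **Resampling.** Time slots are anchored at each individual's first fix,
  spaced 30 minutes apart with a 5-minute tolerance; the nearest
  in-tolerance fix fills each slot and empty slots stay empty. There is no
  interpolation or smoothing anywhere in the package: a gap in the data
  remains a gap in every downstream product.
* **Distances.** All step lengths and displacements are great-circle
  (haversine) distances on a sphere of radius 6371.0088 km. Device error is
  about 8 m, three orders of magnitude above any spheroid correction at
  these scales.

**Migration onset.** Onset is detected from displacement relative to the
wintering reference (the first fix): the first movement bout that carries
the bird at least 50 km from its pre-bout position with a net northward
latitude change. Published workflows state the 50-km northward rule but not
what delimits a "movement", so the bout construction is this package's own
definition: a bout is a maximal run of consecutive steps each of which
*gains* more than 2 km of displacement from the reference. The per-step
gain requirement is what makes the rule sharp: residence jitter gains and
loses a few hundred metres per half-hour step and can never sustain a
2-km-per-step outbound run, while a migratory departure gains tens of km
every step. A weaker rule that merely tolerates small regressions lets the
bout bleed backward into days of winter foraging and blurs the onset by
hours to days. Individuals with no qualifying bout are returned with a
sentinel (`detected = FALSE`), not an error, so incomplete migrations can
be dropped from cohorts.

The analysis window runs from 7 days before onset through 1 August
(inclusive, UTC). For movement modelling the trajectory is additionally
clipped at the individual's incubation initiation date (or the cohort
median for non-attempters) with `clip_to_endpoint()`: a month of
nest-attendance fixes is a third behavioural regime whose near-zero steps
otherwise claim one of the model's states and degrade the flight/stopover
separation.

## Hidden Markov segmentation

Steps between successive fixes carry a gamma-distributed length (mean/sd
parameterization; an optional per-state point mass handles exactly-zero
steps) and a von Mises turning angle (left turns positive; the first angle
of a track is undefined and contributes nothing to the likelihood).
Transition probabilities are either homogeneous or depend on the
device-reported speed covariate (+0.1 km/h offset against zero-inflation)
through a multinomial logit, the convention of the movement-HMM
literature. Models of 1-4 states are supported; the pipeline default is 4
states — roost, forage, local flight, migratory flight — with only the
flight/stopover distinction interpreted downstream. Model order is chosen
by the analyst on interpretability; AIC and pseudo-residual diagnostics are
reported but never auto-select.

Fitting maximizes the forward-algorithm log-likelihood directly
(log-sum-exp scaling in C++; BFGS on unconstrained transformed parameters;
`reltol` 1e-9, default 10 restarts). Restart initializations spread the
state means over quantiles of the observed positive step lengths, with the
top state anchored at the 99.5th percentile — long flights are rare but
extreme, and an initialization that ignores the far tail tends to merge
local and migratory flight. Multiple individuals are pooled as independent
chains sharing parameters; per-individual refits can warm-start from the
pooled fit via `start =`. Fits are bit-reproducible given the seed.
Viterbi decoding breaks ties toward the lower state index.

The speed covariate is supported and tested, but the pipeline-scale
default is the homogeneous fit: on pooled tracks the covariate multiplies
fitting cost several-fold while the step-length separation between
residence and flight already dominates the state assignment.

**Flight/stopover merging.** The migratory state is the one with the
largest mean step length (if the top two means are within 10%, the higher
angular concentration wins). Consecutive migratory steps form candidate
flights; a candidate whose *cumulative* length falls below twice the
migratory mean step (64.6 km for a 32.3 km/step fit) is folded back into
stopover — a single spanned missing fix should not count as a migratory
flight. The threshold applies to segment totals, not single steps
(`per_step = TRUE` gives the stricter variant for sensitivity analysis).
Stopover counts exclude the final stopover, which is the pre-nesting
settlement rather than a refuelling stop; reverse migratory movements are
flight segments with net latitude decrease. Total migration distance sums
all steps from onset through the final flight's end; because the
conventional definition (a plain sum of step lengths) does not say
whether stopover steps count, `flight_steps_only` offers the
flight-only alternative.

## Dynamic Brownian bridge space use

The utilization distribution interpolates occurrence probability between
fixes with Brownian bridges whose motion variance is re-estimated along
the track. Defaults follow the established goose parameterization: window
25 fixes, margin 9, location error 8 m, cells of 10 km² (edge √10 km) on a
spherical Albers equal-area projection (standard parallels 20°/60°,
central meridian 96° W). Equal-area cells are forced by the area
accounting; the grid origin is snapped to cell-size multiples so repeated
runs land on identical grids.

Within each sliding window the leave-one-out likelihood of odd-indexed
fixes (each predicted from the bridge between its neighbours) is
maximized for the motion variance; single candidate breakpoints outside
the margins are compared to the no-break model by BIC, and each between-fix
interval inherits the mean of the window estimates covering its interior.
Tracks shorter than one window fall back to a single global estimate with
a warning.

Each bridge's position density — an isotropic Gaussian with variance
σ²ₘ·T·α(1−α) plus the error terms — is integrated along the bridge with 50
midpoint nodes and deposited on the grid using exact separable Gaussian
cell integrals, then the surface is normalized to mass 1 (always within
1e-9). Fifty nodes keep the along-track discretization below 1e-4 of total
mass per cell on half-hour tracks; the bottleneck is the near-delta density
adjacent to each fix, which converges only first-order in node count.

**Day weighting and composites.** Each cell is weighted by the number of
distinct UTC calendar days with at least one fix in it. "Days spent within
the pixel" is not operationalized in the source workflows; fix-days is the
transparent reading, and cells that carry bridge mass but no fixes get the
model's own residence-time estimate (total tracking days × the cell's mass
share) so transit corridors are down- but not zero-weighted. Weighted UDs
are renormalized, summed across individuals on the shared grid, and
renormalized again — weighting before compositing, so each individual
contributes equal total mass.

**Isopleths and regions.** The mask at level p is the *smallest* cell set
whose mass reaches p: cells in decreasing mass order, ties broken
deterministically by cell index. Masks are nested by construction. High
use is the 50% mask; moderate use is the 80% mask minus the high-use mask
(so high + moderate = the 80% mask; `moderate_base = 0.6` gives the
narrower alternative reading of the 60–80% band). Cells with centroids at
or above 60° N are excluded from area accounting — beyond that line the
birds are moving around nesting areas, not migrating. Per-region areas are
cell counts × 10 km² attributed by centroid point-in-polygon; cells in no
polygon accumulate in an `Unassigned` row that counts toward totals and
percentages but is never ranked.

## Breeding classification

Classification uses only daily movement statistics between 15 May and
30 July — it is fully independent of the HMM. A day's total distance sums
*within-day* steps; the step that crosses midnight belongs to neither
day's total. This matters: an overnight relocation between two quiet sites
would otherwise poison a daily total, whereas the classifier is supposed
to catch it through the site-fidelity requirement instead, mirroring the
field practice of confirming nests by inspecting location clusters.

A nesting attempt is the longest run of consecutive quiet days (total ≤ 2
km) whose fixes also keep ≥ 90% within 250 m of the run's median
coordinate. Runs must reach 6 days (mean clutch 4.1 eggs at 0.8 eggs/day:
shorter quiet spells are egg-laying or loafing, not incubation); a run of
at least 23 days — the minimum published incubation period — is a success,
anything shorter a failure. The 250 m radius is roughly 30× the 8 m device
error, wide enough for nest-relief walks and narrow enough to reject
neighbouring wetlands; it is configurable. One missing day inside a run
neither breaks nor extends it; longer gaps break it (`longest_run = FALSE`
selects the first qualifying run instead, for sensitivity checks).
Failures during egg laying are undetectable by design, and days are UTC
calendar days (`day_offset_hours` shifts the day boundary for local-solar
sensitivity analyses).

Phenology derives pre-nesting duration (incubation start ordinal − arrival
ordinal); strategies split at 10 days — under the capital–income framework
for Arctic geese, an individual that initiates incubation within 10 days
of arrival cannot have rebuilt reserves locally and is classed
capital-leaning. The boundary is strict: exactly 10 days is
income-leaning. Non-attempters receive the lower-median incubation start of
their year's attempters as trajectory endpoint.

## Comparative statistics

Predictors are centred and scaled to unit SD; the wintering region factor
uses the Mississippi Alluvial Valley as reference. Pearson screening flags
pairs with |r| ≥ 0.6 and drops the member later in a configurable priority
order, iterating until no retained pair is flagged. Logistic regressions
are IRLS fits (deviance tolerance 1e-10) scored by
AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1); complete separation and aliased
(rank-deficient) fits are flagged and excluded from averaging with a
message. All-subsets enumeration (≤ 12 predictors) retains models with
ΔAICc ≤ 6, renormalizes Akaike weights over the retained set, and reports
*conditional* model-averaged coefficients: each term averaged over the
retained models containing it, with 95% intervals from the weighted
unconditional-variance estimator. Year enters, when desired, as a fixed
covariate — a random year intercept is deliberately out of scope, matching
the regional-model practice of dropping it under small samples and
convergence trouble. Mann–Whitney U tests are exact when n₁·n₂ ≤ 400 and
the pooled data are tie-free, otherwise normal-approximate with tie and
continuity corrections; one-way ANOVA F-tests are the classical
equal-variance decomposition.

## The synthetic generator

`simulate_population()` emits multi-phase tracks — winter residence,
alternating northward flights and stopovers with occasional
latitude-reversing flights, pre-nesting, then incubation, failure, or
season-long deferral — with state-dependent gamma step lengths, von Mises
headings, dead-reckoned positions (planar locally, re-projected per step)
and 8 m isotropic GPS noise, plus a ground-truth ledger of every planted
quantity. The `"goose2019"` preset targets the movement magnitudes of
midcontinent white-fronted goose spring migration: ~93-day, ~5,450-km
migrations with ~16 stopovers, 32.3 km mean migratory steps, four
wintering regions with a realistic mix, an eastern/western Arctic
destination split, a 55.4% attempt rate and a 71.0% success rate among
attempters. Residence states (roost at night, forage by day, occasional
local flights) are tuned so daily totals sit near 8 km — far above the
2 km quiet threshold — while incubation pins fixes to a nest with 5 m
jitter.

What the generator does *not* emulate — and what passing tests therefore
cannot certify on real data: wind and weather forcing of departures,
energetics, variable fix schedules (beyond optional uniform dropout),
spatially correlated GPS error, habitat selection within stopovers, molt
migration, and any behavioural dependence between individuals. Recovery
results on simulator output are evidence that the estimators invert the
generative assumptions they state, not that real goose data satisfy those
assumptions.

## Numerical choices and degenerate inputs

* Likelihood work is in log space throughout; the forward recursion uses
  log-sum-exp scaling, von Mises normalization uses exponentially scaled
  Bessel functions, and κ is capped at e^6.5 to keep Bessel evaluation
  finite.
* Gamma parameters, κ, and zero masses are optimized on log/logit scales;
  transition rows are multinomial logits with the diagonal as reference.
* Viterbi ties go to the lower state index; isopleth ties at the cut go to
  the lower cell index; the lower median is used for even-count cohort
  endpoints.
* Duplicate timestamps keep the first occurrence, by design not
  configurable. Empty results are errors where silence would corrupt
  downstream stages (all fixes filtered, empty window, zero-mass UD) and
  sentinels where the caller must branch (no onset, no attempt).
* Zero-length steps have undefined bearings; their turning angles (and the
  following step's) are treated as missing.

## Scales used by the test suite

The suite checks parameter recovery at the sizes where the asymptotics it
relies on are comfortably in force while a full run stays in the minutes
range: 4-state fits on 4,000-step series over 20 seeds (migratory mean
within 15%), 2-state fits on 2,000 steps (means within 10%), Viterbi
against exhaustive enumeration on ≤ 10-step, ≤ 3-state instances,
motion-variance recovery on 200-fix Brownian tracks over 20 seeds (median
within 25%), breeding-scenario recovery on cohorts of 200 simulated
individuals (exact when noiseless; incubation onset within ±1 day in ≥ 95%
of attempts at 8 m noise), and 1,000-replicate type-I calibration of the
ANOVA F-test. The acceptance script runs the full chain on a 56-individual
cohort, the emulated study scale, fitting the pooled movement model on a
3-individual subset and building composite space use for 2 individuals.

## Known limitations

* The motion-variance estimator is mildly biased low on rough tracks (the
  leave-one-out construction conditions on neighbouring *observed* fixes);
  the 25% recovery tolerance reflects that.
* Segmentation counts include the leading winter-residence segment as a
  stopover; published counts constructed the same way share this
  convention, but comparisons against counts that start at onset need the
  obvious −1.
* The flight threshold is self-referential (twice the fitted migratory
  mean); two datasets segmented with separately fitted models use
  different absolute thresholds.
* All-subsets averaging is exponential in the predictor count and
  deliberately capped at 12 predictors.
* Breeding classification cannot see egg-laying failures, renesting, or
  brood fate; its endpoint is incubation initiation.
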