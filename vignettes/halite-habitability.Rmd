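---
title: "Deliquescence habitability windows and salt-in signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deliquescence habitability windows and salt-in signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halohab)
library(dplyr)
```

halohab analyses transplant experiments on the microbial communities that
colonize halite (NaCl) nodules in hyper-arid salt flats. These communities
have no access to liquid water except the brine formed when the salt
deliquesces: NaCl absorbs atmospheric water vapor and forms a saturated brine
once relative humidity reaches its equilibrium value of about 75 % RH. The
package turns microclimate logger records into daily "habitability windows",
quantifies how community composition restructures across sites with different
moisture regimes, and measures the functional signatures of salt-in
osmoadaptation (acidified proteomes, Trk potassium transport). A synthetic
data generator reproduces the statistical structure the analysis assumes, so
every stage is testable without field or sequencing data.

## 1. From logger records to habitability windows

### Daily smoothing and the 3-minute grid

Loggers record temperature, RH and photosynthetically active radiation (PAR)
every 30 minutes, but different sensors are not synchronized. Readings are
aligned by fitting, per calendar day and per variable, a penalized regression
spline of the value against time of day and evaluating it on a common 3-minute
grid starting at midnight (480 points per day; minutes 0, 3, ..., 1437, a
half-open day).

Numerical choices:

* The smooth is a cubic penalized regression spline (`mgcv`, `bs = "cr"`) with
  basis dimension `k = min(20, n - 1)` and maximum-likelihood smoothness
  selection. With 48 readings per day, 20 basis functions resolve diurnal
  structure (including fog humps a few hours wide) without chasing noise; on
  noiseless sinusoids sampled every 30 min the gridded values are within a few
  hundredths of the analytic curve, and the error shrinks further as sampling
  density grows (both are property-tested).
* The basis is non-cyclic and days are fitted independently; no continuity is
  imposed across midnight. Day boundaries are the UTC calendar date of the
  timestamp; timezone comes from the input, never from inference.
* Constant days short-circuit to an exact constant (the smoother would
  otherwise return the constant only up to numerical noise).
* A day-variable series needs at least 4 non-missing readings; thinner days
  are omitted from the grid with a warning. Variables are smoothed
  independently, so a day can be present for RH but absent for PAR.
* RH grids are clipped to [0, 100] and PAR to >= 0 *after* smoothing —
  splines happily overshoot near saturation.

Daily summaries (min/max/mean) are computed on the grid, and replicate nodules
are averaged pointwise per site/position/date, recording how many replicates
contributed.

### Thresholds and wet hours

A 3-min grid point is *wet* when RH is at or above the deliquescence threshold
(75 % RH inside nodules; 95 % RH for outside air, where fog and dew form
slightly below saturation), and *lit* when PAR >= 0.01 µmol photons m⁻² s⁻¹,
the minimal irradiance usable by highly adapted phototrophs. Daily wet (and
wet + light) hours are the count of qualifying grid points times 0.05 h; no
interpolation of threshold-crossing times is attempted. Comparisons are
inclusive (`>=`) by default — the threshold value itself is the equilibrium
point, and readings sitting exactly on it indicate brine — with a
`strict_inequality` flag to flip every comparison at once.

Two counting paths are exported: `habitability_days()` on the spline grid
(0.05 h per point), and `habitability_from_readings()` directly on raw
readings (0.5 h per reading at 30-min cadence). The two agree on noiseless
data; the raw path is preferred for very long records where per-day spline
fits add cost but no information, and is what the packaged regime analyses
use. Which path produced any given table is visible from its provenance.

### Wet/dry period segmentation

A day is wet when its wet hours reach `wet_day_min_hours` (default 1 h — one
sustained fog event; a couple of stray grid points should not make a wet
day). Runs shorter than `min_run_days` (default 7) are absorbed into the
surrounding state, shortest runs first, so isolated blips do not fragment the
record; the returned periods tile the record exactly. Both defaults are
configurable — the segmentation is a descriptive device, not a fitted model.
A gap in the dates is an error instructing the caller to fill or split the
record, rather than silently bridging climatically distinct fragments.

## 2. The synthetic microclimate generator

`simulate_air_series()` produces the *air* record: a sinusoidal temperature
cycle peaking at 15:00, an anti-phased RH cycle, Gaussian sensor noise,
nocturnal fog events (with per-night probability) that lift RH toward a peak
value on a half-sine hump between 00:00 and 08:00, rain days on which RH is
forced to saturation, and a daylight half-sine PAR curve. Fog as a nocturnal
RH lift and rain as forced-saturation blocks are deliberately minimal: the
target phenomena are "RH exceeds a threshold for some hours", not cloud
physics.

`simulate_nodule_series()` runs a bucket model for the nodule interior at the
sensor cadence: a dimensionless brine reservoir in [0, 1] recharges at
`recharge_rate` per hour whenever air RH is at or above the deliquescence
point and evaporates at `evaporation_rate` otherwise. While the reservoir
holds brine, interior RH is buffered at the deliquescence point; after
exhaustion it relaxes exponentially (half-life `relaxation_halflife_h`)
toward the ambient air RH. Interior temperature copies air temperature (field
sensors show the two agree closely), interior PAR is zero at middle/bottom
positions and fixed at 1 % of air PAR at nodule tops — interior light levels
are never reported in field data, only that lit windows exist at tops, so 1 %
is a placeholder magnitude that preserves the day/night pattern.

One modeling detail matters for threshold counting: the buffered interior RH
is `deliquescence_rh + buffer_offset` (default +1 % RH) plus noise, not the
deliquescence point exactly. Field records of brine-filled nodules read "near
75 %" *and* wet around the clock; a sensor reading centred exactly on 75 with
symmetric noise would fall below an inclusive >= 75 threshold half the time,
which is an artifact of putting the threshold on top of the noise centre, not
a property of the system. The offset represents the slight supersaturation /
sensor bias implied by continuously wet readings; set `buffer_offset = 0` to
study the knife-edge case.

Three named presets (`regime_params()`) encode the contrasting regimes the
analysis is designed around, and are fixed once:

* **constant_wet** (120 days): humid coastal air (RH 70 ± 20 %), fog on 70 %
  of nights; evaporation (2e-4 h⁻¹) is far slower than recharge, so the
  interior stays buffered the whole record — every day 24 wet hours.
* **cycling** (330 days): dry altiplano air (RH 35 ± 15 %), no fog, two-day
  precipitation events beginning at days 10, 160 and 280. Evaporation
  7.5e-4 h⁻¹ drains a full reservoir in ~55 dry days, so each recharge
  sustains one wet period: three wet periods separated by two long dry
  spells. The record ends during the third wet period; a full-year record
  would append a trailing dry tail and a sixth period.
* **progressive_dry** (200 days): equally dry air, *no* recharge at all and a
  half-full reservoir draining over ~100 days; wet hours are 24 until
  exhaustion, fall to zero within days, and never recover — a monotone
  decline.

The generator is a pure function of (parameters, seed): a single RNG is
seeded per call via `withr::with_seed`, and identical inputs give identical
series. What it does **not** emulate: radiative or thermodynamic microclimate
physics, brine chemistry beyond a fixed deliquescence RH, sensor drift or
dropouts, and spatial heterogeneity within a nodule. Passing regime tests
therefore demonstrates that the *analysis chain* recovers the structure the
model generates, not that the bucket model is a calibrated physical model of
any particular field site.

## 3. Community restructuring statistics

Count tables (contigs or MAGs by sample) are normalized per sample to percent
(`normalize_relative_abundance()`, idempotent, errors on all-zero samples).
On top of that sit the standard ecology statistics:

* **Archaea:bacteria ratio** per sample, `sum(archaeal %) / sum(bacterial %)`;
  features from other domains are excluded from the ratio but reported, and a
  zero-bacteria sample yields `Inf` with a warning rather than an error — in
  a salt-in-dominated community that outcome is informative, not invalid.
  Site values are means over the site's samples.
* **MAG quality filter**: completeness >= 70 % and contamination <= 5 %, both
  bounds inclusive (a genome *at* the published cutoff passes it).
* **Species dereplication**: genomes with ANI >= 95 % and aligned coverage
  >= 10 % (inclusive) are the same species; clusters are single-linkage
  connected components of that graph — the usual greedy-dereplicator
  behavior, and the most permissive choice, made explicit and pluggable via
  the thresholds. Representatives maximize `completeness − 5·contamination`
  (the familiar dereplication score), ties broken by input order.
* **Specialized MAGs**: mean relative abundance strictly above 10 % in at
  least one site ("higher than" is a strict inequality; a MAG at exactly
  10 % everywhere is not selected).
* **Bray–Curtis** dissimilarity `d(i,j) = Σ|x_ki − x_kj| / Σ(x_ki + x_kj)`
  via `vegan::vegdist`; the test suite re-derives it by hand (including the
  worked value 3/11 for profiles (1,2,3) vs (2,2,1)) so the wrapper cannot
  silently change meaning.
* **PCoA** by classical Torgerson scaling (`stats::cmdscale`): double-centre
  −½D², eigendecompose, keep positive-eigenvalue axes; variance explained is
  reported over positive eigenvalues and negative ones (expected for
  Bray–Curtis) are kept in the result rather than hidden. On genuinely
  Euclidean input the embedding reproduces the distances to 1e-8, which is
  the main correctness test.
* **ANOSIM**, authored in-package: upper-triangle dissimilarities are ranked
  with midranks for ties, and `R = (r̄_between − r̄_within) / (n(n−1)/4)`,
  the classical scaling that confines R to [−1, 1]. The p-value uses the
  add-one convention `(1 + #{R* ≥ R}) / (1 + n_perm)` under random
  relabelings; `exhaustive = TRUE` enumerates all n! relabelings (n <= 8)
  and returns the exact exceedance fraction with the observed labeling
  included. The implementation is cross-checked against `vegan::anosim` (R
  statistic) and against a brute-force enumeration oracle in the tests.
* **Welch's t** via `stats::t.test(var.equal = FALSE)`, two-sided (sidedness
  is a convention; two-sided is the conservative default). The degenerate
  both-constant-equal-means case returns t = 0, p = 1; both-constant with
  unequal means is an error. No multiple-testing correction is applied by
  default — downstream users comparing many taxa should apply
  `p.adjust(..., "BH")` themselves.

`simulate_community()` closes the loop for testing: per-taxon log-weights are
drawn once, salt-in taxa get an extra `dryness_sensitivity × dryness_index`
term per site, and replicate compositions come from a Dirichlet with mean
`softmax(log-weights)` and total concentration `dirichlet_concentration`
(default 200 — replicate scatter of a few percentage points on dominant taxa,
comparable to between-nodule variability). Salt-in taxa are labeled archaeal
*Euryarchaeota* so the taxonomic statistics see the shift the generator
encodes. The generator returns proportions (summing to 1); piping through
`normalize_relative_abundance()` gives the percent scale used everywhere
else.

## 4. Proteome signatures of the salt-in strategy

Salt-in halophiles accumulate molar KCl and carry proteomes enriched in
acidic surface residues, visible as a downward shift of the isoelectric-point
(pI) distribution. The pI engine is a Henderson–Hasselbalch charge model:

$$Z(\mathrm{pH}) = \sum_{b \in \{H,K,R,\mathrm{Nterm}\}} \frac{n_b}{1 + 10^{\mathrm{pH} - pK_b}} \;-\; \sum_{a \in \{D,E,C,Y,\mathrm{Cterm}\}} \frac{n_a}{1 + 10^{pK_a - \mathrm{pH}}}$$

Ambiguous residues (X, B, Z, U, O) are charge-neutral. Z is strictly
decreasing in pH with Z(0) > 0 > Z(14), so the pI is the unique root,
found by bisection on [0, 14] (stop at |Z| < 1e-4 or bracket < 1e-6 pH
units; the bisection is vectorized over sequences via residue counts, so
thousands of proteins cost milliseconds). The tests compare it against an
independent fine-grid charge scan at 1e-4 resolution.

pKa constants default to the EMBOSS set, with the Sillero set as an
alternative (`pka_set()`). Published pKa tables differ enough to shift
absolute pI by ~0.1–0.3 units, so cross-tool comparisons of community mean pI
are only meaningful within one set; shifts *between* communities are robust
to the choice.

The community signature is the weighted mean pI, `Σ w_i pI_i / Σ w_i`, with
weights defaulting to each protein's parent-contig relative abundance (equal
weights when no weight column is present). Weighting by abundance rather than
protein length or read depth reflects that the signature should track *which
organisms dominate*, not how long their genes are.

Trk potassium-transport potential is the per-sample summed relative abundance
of features annotated with the Trk KOs (trkH = K03498, trkA = K03499); a
feature carrying both counts once. The osmoadaptation catalog
(`osmo_gene_catalog()`, shipped as an editable TSV) groups marker genes into
six strategies — potassium uptake, sodium:solute symport, compatible-solute
uptake (OpuA/OpuC/OpuD/OpuBD/BetT), glycerol utilization (glpK + GlpABC),
trehalose biosynthesis (glgA/glgC/treX) and ectoine biosynthesis
(asd/ectB/lysC) — and a strategy is *complete* in a genome only when every
member gene is present (a kinase without its dehydrogenase does not confer
glycerol catabolism). The catalog loader rejects malformed gene symbols and
genes assigned to two strategies.

`simulate_proteome()` draws sequences i.i.d. from a 20-letter composition in
which D/E frequencies are multiplied by `1 + acidic_bias` before
renormalization — the minimal model that moves the pI distribution without
entangling length or abundance effects. Real proteomes are of course not
i.i.d. residue strings; the generator supports tests of the *signature
pipeline* (direction and detectability of the shift), not of biological
realism.

## 5. Problem sizes, determinism, reproducibility

The packaged analyses and tests run on deliberately desk-scale problems:
regime records of 120–330 days at 30-min cadence, spline gridding exercised
on multi-day windows, communities of 40 taxa × 8 samples with 999-permutation
ANOSIM, proteomes of a few hundred sequences, and oracle comparisons on up to
1,000 random sequences. These sizes make the full suite run in about a
minute while leaving every algorithmic path exercised; all scale linearly if
pointed at year-long multi-site records.

Every stochastic function takes its seed explicitly (in its parameter object
or as an argument) and restores the caller's RNG state, so pipelines are
reproducible end to end; `run_report()` writes every table with a provenance
header (package version, seed, configuration hash) and re-runs are
bit-identical for fixed seed and configuration.

## 6. Known limitations

* The bucket model has one reservoir per nodule position and a single fixed
  deliquescence point; mixed-salt systems with composition-dependent
  deliquescence are out of scope.
* Wet/dry segmentation is threshold-plus-run-length, not a hidden-state
  model; for records with gradual transitions the period boundaries shift
  with `wet_day_min_hours`.
* The spline gridding fits each day independently, so values just after
  midnight can be discontinuous with the previous day's fit; daily summaries
  and wet-hour counts are insensitive to this, but the grid should not be
  used as a continuous multi-day signal.
* Taxonomy, KO annotations and MAG quality metrics are *inputs*; the package
  deliberately implements no sequence-level inference.
* ANOSIM p-values are bounded below by the number of distinct relabelings;
  with very few samples per group the test cannot reach conventional
  significance regardless of separation.
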