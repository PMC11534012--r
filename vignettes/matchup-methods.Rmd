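---
title: "Methods: satellite-in situ matchup construction for estuarine water quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: satellite-in situ matchup construction for estuarine water quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estuaryscope)
```

## The problem

Predicting chlorophyll and harmful algal blooms from multispectral imagery
requires large databases that pair in situ water-quality observations with
satellite surface reflectance at the same place and time. Building such a
database for small estuaries and tidal rivers raises three methodological
problems that this package addresses as reusable, tested components:

1. **Harmonization.** Monitoring programs export the same physical
   measurement under different column names, units, time zones, depth
   conventions, method labels and QA vocabularies. These "dialects" must be
   mapped onto one canonical schema without silently corrupting values.
2. **Matchup quality.** A 10 m-resolution reflectance pixel near a shoreline,
   under a cloud, inside a cloud shadow, or in sun glint does not measure the
   water column. Matchups need spatial admission rules, masks, and
   homogeneity filters before they are trusted.
3. **Stratification.** Chlorophyll algorithms behave differently across
   optical water types (OWTs) and trophic states, so matched spectra are
   classified -- by chlorophyll concentration into trophic classes and by
   fuzzy clustering of spectral shape into OWTs -- and the OWTs are related
   to water-quality drivers with a nonparametric discriminant rule.

Because the real database derives from tens of live data sources and a
cloud imagery archive, the package is driven by a **synthetic-world
generator** with planted ground truth: every downstream verdict (a rejected
record, a masked pixel, a recovered cluster) can be checked against what
was planted.

## Pipeline and default thresholds

`run_pipeline()` executes: synthesis → harmonization → site screening →
temporal pairing → masking/extraction → QA filters → classification →
discriminant analysis. Every numeric threshold lives in
`pipeline_config()` with the published protocol values as defaults:

| parameter | default | meaning |
|---|---|---|
| `radius_m` | 30 m | matchup disc radius and site-location error buffer |
| `window_h` | 24 h | temporal half-window for observation-scene pairs |
| `water_threshold` | 0.80 | minimum historical water-occurrence fraction |
| `cloud_prob_threshold` | 0.20 | pixel masked when cloud probability >= 20% |
| `min_valid_pixels` | 9 | minimum valid 10 m pixels in the disc |
| `max_median_cv` | 0.15 | maximum median CV over aerosol/blue/green/red |
| `outlier_k` | 1.5 | outlier cut (mean +/- k.SD) before the CV |
| `shadow_heights_m` | 200-2000 m | cloud-top heights swept by the shadow projection |
| `glint_angle_threshold_deg` | 40 | specular cone flagged as potential glint |
| `road_buffer_m` | 15 m | half-width of the road/causeway exclusion buffer |
| `knn_k` | 4 | neighbourhood of the discriminant rule |
| `bricker_bounds` | 5, 20, 60 ug/L | trophic-state class bounds |

### Spatial admission

Sites are admitted into an estuary when they fall inside its polygon
buffered by 30 m -- the buffer absorbs recorded-position error -- with ties
between overlapping buffers resolved to the nearest boundary. A site is
*edge-excluded* when the closed 30 m disc about it touches the shoreline or
a buffered road (bridges and causeways shade and contaminate edge pixels).
Because estuarine margins flood and drain with the tide, pixels must also
have been classified as water at least 80% of the time; the default reads
this per pixel (every disc pixel must pass), with `water_rule = "mean"`
available for the laxer disc-average reading. Both readings are
monotone in the threshold, which the property tests exploit.

### Masks

* **Cloud**: probability >= 20% masks the pixel. The threshold is
  deliberately conservative; the `>=` convention keeps the boundary pixel
  masked.
* **Cloud shadow**: the cloud mask is translated along the anti-solar
  azimuth by `h * tan(sun_zenith)`. Cloud-top height `h` is unobserved, so
  the projection sweeps 200-2000 m in 100 m steps and takes the union --
  over-masking is accepted. No near-infrared darkness condition is applied:
  dark water is indistinguishable from shadow in the NIR, and requiring low
  NIR would misclassify the very pixels of interest.
* **Glint**: the viewing geometry is flagged when the view direction lies
  within a 40 deg cone of the sun's specular reflection off a flat surface.
  The cone half-angle is configurable; 40 deg makes near-nadir views of a
  high sun glint-prone, which is the physically conservative choice.

### Extraction and QA

For each admitted pair, pixel values of all 13 bands are collected over
unmasked pixels whose centres lie in the disc (centre-of-pixel convention).
The matchup keeps the per-band median and SD. The record is accepted iff
at least 9 valid 10 m pixels were available, the median coefficient of
variation across the aerosol, blue, green and red bands is <= 0.15 after
discarding values beyond mean +/- 1.5 SD per band, and the scene is not
glint-flagged. Each rejected record carries exactly one primary reason
(`low_n` > `glint` > `degenerate` > `high_cv` in precedence), so stage
counts are conserved. Two numerical choices: a CV whose filtered mean is
zero is `degenerate` (relative spread is meaningless), and the CV
comparison uses a 1e-12 epsilon so a median CV of exactly 0.15 is accepted
despite floating-point noise.

## Classification

**Trophic state.** Chlorophyll maps into Low (0, 5], Medium (5, 20],
High (20, 60] and Hypereutrophic (60, inf) ug/L. The intervals are
half-open with the upper bound belonging to the lower class, so 5 -> Low
and 20 -> Medium; this matches the printed class bounds of the indexing
method the defaults follow.

**Optical water types.** `fuzzy_cmeans()` implements the standard
alternating updates (memberships `u_ij = 1 / sum_l (d_ij/d_il)^(2/(m-1))`,
centres as `u^m`-weighted means) with fuzzifier `m = 2`, tolerance 1e-6 on
the maximum centre shift, and a crisp-membership guard for profiles
coincident with a centre. Initialisation is random from the data with the
best objective over 10 starts kept, because fuzzy c-means is
initialisation-sensitive. The fuzzifier, the absence of standardization of
the band medians, and the number of restarts were genuinely open choices:
`m = 2` is the conventional default, spectra are clustered on raw medians
because magnitude differences *are* the dominant optical signal here
(z-scoring is available via the caller), and 10 restarts makes the best
objective stable on the problem sizes used.

**Cluster-count selection.** `validity_indices()` computes eight standard
indices: partition coefficient, partition entropy, modified partition
coefficient, Xie-Beni, Fukuyama-Sugeno, partition density, average
partition density, and a compactness/separation index `si` (mean fuzzy
within-cluster scatter divided by the squared distance to the nearest
other centre; minimal at the optimum). The density indices use *diagonal*
fuzzy covariances with a 1e-12 ridge: full covariance determinants
underflow on near-noiseless, effectively low-rank spectra. Index
definitions vary in the literature -- particularly the density and
separation families -- so the implemented formulas are documented here and
versioned with the package rather than asserted to be anyone else's.
`select_k()` fits every candidate k, lets the named criteria
(Fukuyama-Sugeno, average partition density, `si` by default) vote, and
resolves ties toward the smaller k. On noiseless planted spectra the
density indices degrade (they reward vanishing within-cluster volume and
so prefer large k), which is why selection uses a majority rather than any
single index.

## Discriminant analysis

The nonparametric discriminant rule classifies a point by its `k = 4`
nearest neighbours on unit-variance-standardized features, with
posteriors proportional to prior-weighted neighbour counts (uniform priors
by default; proportional available). Distance ties at the k-th neighbour
include all tied points; posterior ties resolve to the lower-indexed
class and are flagged. Error rates are estimated by leave-one-out
(self excluded): per-class error is the misclassified fraction within the
class and the overall rate is the prior-weighted combination. LOO was
chosen over resubstitution because resubstitution is optimistically biased
for memory-based rules; the original tooling this emulates does not state
its estimator, so the defensible default is used and reported as such.
`stepwise_select()` adds, at each forward step, the variable minimizing
the overall LOO error and emits the full candidate-by-step error matrix
in the layout of the published error-rate tables.

## What the synthetic generator emulates -- and what it does not

`make_world()` builds a planar estuary (metres; no geodesy, since every
distance in the protocol is <= tens of metres), smooth correlated true
fields (lognormal chlorophyll around a 5 ug/L median, a longitudinal
salinity gradient, temperature, dissolved oxygen anti-correlated with
chlorophyll, turbidity), four bio-optical archetype zones, a
water-occurrence raster decaying toward shore, and stratified sampling
sites; four of five sites are placed >= 60 m from shore, as monitoring
networks favour navigable open water, and the rest are unconstrained so
the edge screens have work to do. `render_scene()` renders water pixels
through the forward model below, calibrates a smoothed-noise
cloud-probability field so the requested fraction of pixels exceeds
probability 0.5, projects shadows geometrically from a 1000 m default
cloud deck, and keeps the true masks on the scene for verification.
`emit_insitu_sources()` renders canonical truth through per-source
dialects (local clocks, Fahrenheit, coded depths, letter or numeric QA
codes) and plants corruptions at 5% each -- QA failures, missing times,
missing depths, relative-fluorescence-only chlorophyll, duplicates -- plus
2% ambiguous method labels, each tagged with the harmonization rule
expected to catch it.

The forward model gives each archetype baseline reflectance
`mag * hump(lambda)` peaking in the green (560 nm) plus a lesser red-edge
(705 nm) peak, with chlorophyll coupled to the 705 nm band through a
saturating term `0.3 * mag * chl / (chl + 50)`; archetypes differ mainly
in overall magnitude `mag` in {0.02, 0.04, 0.07, 0.10}. This reproduces
the qualitative spectral pattern of CDOM-dominated coastal waters -- the
green peak, the secondary red-edge peak, magnitude separation between
types -- and nothing more. There is no radiative transfer, no atmosphere,
no sensor model, no resampling across native band resolutions (all bands
are rendered at 10 m), and no tidal dynamics. Passing tests therefore
demonstrate that the *pipeline logic* is correct under a world whose
ground truth is known; they do not validate any bio-optical retrieval
against real water.

## Problem sizes and determinism

The default demo world is 64 x 64 pixels at 10 m with 24 sites and 10
scenes, sized so a full pipeline run takes a few seconds and the whole
test suite stays around a minute; the acceptance script runs the same
sizes. All randomness flows from one root seed: worlds, scenes and
exports each derive fixed offsets from it, and regenerating with the same
seed is bit-identical, which the tests assert via serialization.

## Known limitations

* Planar geometry only; real deployments must project coordinates before
  using the spatial operations.
* The per-pixel water-persistence rule is stricter than the disc-mean
  reading; which one the original workflow used is not stated, so both are
  provided and the conservative one is the default.
* When duplicate records disagree in value, the first in stable input
  order is kept -- the source protocol states deduplication without a
  tie-break rule, so the choice is arbitrary but deterministic and logged.
* The density-based validity indices are unreliable on noiseless or
  low-rank profiles (see above); the selection consensus mitigates but
  does not remove this.
* Scene rasters are exchanged as plain TIFF plus a JSON sidecar rather
  than georeferenced GeoTIFF; the sidecar carries time and geometry, not a
  CRS.
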