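---
title: "Methods: combined heat and land-use exposure modelling in heatland"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combined heat and land-use exposure modelling in heatland}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatland)
```

`heatland` projects, species by species, how much of a terrestrial
vertebrate's current range becomes unsuitable through the century because of
extreme heat events, land-use change, or both. This vignette documents the
model, its assumptions, the tunable parameters, the synthetic-data design,
and the numerical decisions — in particular the places where the underlying
methodological choices were genuinely open and the package had to commit to
one reading.

## 1. The analysis grid and range rasterization

All stages run on an abstract equal-area lattice (`build_grid()`); the
default 24.125 km cell edge gives the 582.02 km² cell used in global
Behrmann-projection analyses. The package deliberately carries no coordinate
reference system: range inputs are per-cell overlap fractions
(`rasterize_range()`), which decouples the science from any particular GIS
stack. Two gridding rules apply:

* a species whose whole polygon is smaller than one cell keeps **every**
  touched cell (otherwise tiny-ranged species would vanish from the grid);
* larger ranges keep cells with overlap ≥ 10 % — the exclusion is strictly
  "below 10 %", so a cell exactly at the threshold is kept.

A large range none of whose cells reaches 10 % would otherwise become empty;
the package keeps the single best-covered cell and warns, so every species
remains analysable. This case cannot arise from real polygon rasterization
(the fractions then sum to the polygon area) but can from hand-built inputs.

## 2. Thermal limits and extreme heat events

The realised thermal limit of a species is the spatial maximum over its
range of the per-cell 99th percentile of daily maximum temperature over
1950–2005. Percentiles use linear interpolation between order statistics
(`stats::quantile` type 7) — the common analytical default; the type is an
argument of `thermal_limit()` so sensitivity to the quantile rule can be
checked, and the test suite pins the type-7 value on a known series.

An extreme heat event is a run of **more than five consecutive days**
strictly above the limit: run length ≥ 6, and exceedance is strict
(`value > t_star`), both literal readings of the event definition. Three
per-cell-per-year metrics summarise events:

* **frequency** — number of qualifying events;
* **duration** — length of the longest event (alternative: total event days,
  `duration_rule = "total"`);
* **intensity** — maximum °C exceedance over event days (alternative: mean
  of per-event peaks, `intensity_rule = "mean"`).

The longest/maximum pair is the default because it tracks the most damaging
single episode; both alternatives are config switches because the exact
operationalisation is a methodological free choice. Runs crossing 31
December are split at the year boundary — metrics are defined per
cell-year, and a no-leap 365-day calendar is used throughout (the convention
of downscaled daily climate products; it also makes every year the same
length, which the vectorised run scanner exploits).

A future cell-year is *unsuitable* when any metric **strictly** exceeds the
species' own 1950–2005 maximum over all its range cells; equality stays
suitable ("higher / longer / greater" read as strict). A direct consequence,
verified as a property: no baseline cell-year can be unsuitable under its
own species' baseline maxima.

One spec-level intuition deserves correction: uniform warming does **not**
monotonically increase event *frequency*. Warming can flip the single cool
day separating two six-day runs, merging them into one event (frequency
2 → 1). Longest duration, total event days and peak intensity are genuinely
monotone under uniform warming, and the property tests assert exactly that
monotone set.

### Ensemble handling

Per-model binary verdicts are combined by the median of the flags —
unsuitable iff a strict majority of models say so. The median of an even
binary set is ambiguous, so the ensemble size must be odd; the synthetic
default is 3 pseudo-GCMs (5 for full-scale runs). An alternative — taking
medians of the metrics before thresholding — was considered and rejected as
the default because the binary-median is the more conservative and more
common ensemble rule; the per-model metrics are retained internally so the
alternative can be built from the same pass.

## 3. Suitable-area trajectories

Land use enters through the 12 LUH2 fractional states collapsed to five
classes (`reclassify_luh2()`): forest (primf + secdf), non-forest
(primn + secdn), agriculture (the five crop types), managed
(pasture + rangeland), urban. IUCN habitat codes map onto the same five
classes (`reclassify_iucn_habitats()`); codes for caves, marine/aquatic
habitats, introduced vegetation, other and unknown are dropped. Two mapping
choices were open and are configurable through the mapping vector: rural
gardens (14.4) are mapped to urban as a global rule, and terrestrial
wetlands (5) to non-forest (dropping them is a one-line substitution).
Per-cell class sums below 1 (water/ice) are accepted and habitat fractions
are **not** renormalised: suitability is an absolute land fraction.

The annual suitable area of a species is the cell-area-weighted sum over its
range of (binary climate flag) × (preferred-habitat fraction). Mixing a
binary climate state with a fractional land-use state is a deliberate
asymmetry: heat either did or did not break the species' historical envelope
in a cell, while habitat genuinely occupies a fraction of it. SA₂₀₁₅ assumes
suitable climate everywhere; climate masking starts in 2020, with 2015–2019
a land-use-only spin-up. Recolonisation is instantaneous: a range cell
counts again the year its land use turns suitable, regardless of adjacency —
an explicit best-case assumption that overestimates persistence but flags
future opportunity areas. The extinction rule is absorbing: the first year
with zero suitable area zeroes everything after it, even if conditions
recover; the rule is idempotent, which the tests exercise on random
trajectories.

Percent change is asymmetric by construction: gains are scored against the
*future* area, (1 − SA₂₀₁₅/SAᵧ)·100 ∈ (0, 100); losses against the
*baseline*, (SAᵧ/SA₂₀₁₅ − 1)·100 ∈ [−100, 0). The "0–200" exposure scale is
implemented as the signed percent plus 100: 0 = total loss, 100 = no change,
gains approach but never reach 200. The shift is the only reading that makes
the two equations produce a single bounded index; both the signed and the
shifted value are emitted. `exposure_fraction` is the loss side as a 0–1
fraction, which is also what the regression models.

### Driver attribution and its dominance structure

Two counterfactual trajectories accompany the combined run: *climate-only*
(habitat frozen at 2015 fractions, only the climate mask moves) and
*land-use-only* (climate ignored). A species whose combined exposure reaches
the threshold (default 0.5) is attributed to `heat` if the climate-only run
alone reaches it and land-use-only does not, `landuse` for the reverse,
`both` when each driver alone suffices, and `combined_only` when only the
union does. `both` is tabulated as its own class rather than folded into
either driver; `attribution_summary()` reports shares over all attributed
species.

When land use only ever *removes* preferred habitat, combined SA ≤
min(single-driver SA) holds for every species-year — unsuitability is then a
union of two masks — and combined exposure dominates both single-driver
exposures, which is exactly the "more-than-additive" pattern expected when
heat and conversion strike different parts of a range. The package's
dominance test runs on a synthetic world whose species all prefer natural
(declining) habitat, where the inequality must hold without exception. It is
**not** universal: where land use *gains* habitat in climatically suitable
cells, the combined trajectory can exceed the frozen-2015 climate-only one —
this is the compensation effect visible under sustainability-type scenarios,
and it is expected behaviour, not a defect.

## 4. Cell summaries and bivariate classes

Per cell: the mean (over resident species) percent change of each species'
preferred-habitat fraction in that cell (window mean, default 2091–2100,
against 2015), and the proportion of resident species whose ensemble flag is
unsuitable there in at least one window year. "At least one window year" is
the default exposure criterion (a majority-of-window alternative is an easy
variant); species extinct before the window closes count as exposed in all
their cells, since the map describes exposure of *current* ranges. Cells
whose species had no habitat there in 2015 score 0 (none then, none later)
or the +100 gain limit (habitat from nothing).

The 3×3 bivariate class crosses land-use change (edges −5 %, +5 %) with
climate exposure (edges 0.25, 0.5). The edges are honest config defaults —
no published binning exists to match — and boundary values fall in the lower
bin. Land-use change 0 therefore sits in the neutral *centre* column, which
is also what makes the null world (below) land every occupied cell in the
centre/lowest class.

## 5. The zero-one inflated beta regression

Exposure fractions at 2100 live on [0, 1] with genuine point masses at 0
(no loss) and 1 (total loss; species extinct before 2100 enter with y = 1).
The ZOIB mixture used is the conditional parameterisation: P(y = 0) = p₀,
P(y = 1 | y > 0) = q₁, and Beta(μφ, (1 − μ)φ) on the interior, with logit
links for p₀, q₁ and μ on a shared design (intercept, log10 range area, Red
List indicators with LC as reference; an ordinal threat-score coding is
available) and a single log-precision φ. This is the standard ZOIB
parameterisation; nothing in the analysed problem pins a different one.

The likelihood factorises exactly into the two Bernoulli layers and the beta
layer, so `fit_zoib()` estimates the Bernoulli layers by logistic regression
and the beta layer by BFGS from a deterministic start (logit of the interior
mean, zero slopes, φ = 1); the combined result is the joint maximum
likelihood estimate, with standard errors from the respective information
matrices and a finite-difference gradient norm reported for the beta layer.
Degenerate layers (all zeros, no ones, no interior points) are flagged as
boundary cases — coefficients pushed to ±∞ — rather than raised as errors.
Recovery is tested at n = 2000 over 200 simulation replicates: every
coefficient's mean bias stays below 0.1 and at least 90 % of estimates fall
within 3 standard errors of truth.

## 6. The synthetic world

`generate_world()` emulates the three global data sources on the analysis
grid, deterministically from a single seed:

* **Land use** — per-cell 12-state compositions from Dirichlet-style draws
  with a west–east forest gradient, land totals between 0.88 and 1 (the
  remainder standing for water/ice), then an annual conversion process:
  under positive trend rates a fixed fraction of remaining natural land
  moves to cropland (60 %), pasture (25 %) and urban (15 %) each year; under
  a negative rate agriculture returns to secondary vegetation. Default rates
  (−0.002, 0.0015, 0.006, 0.0025 yr⁻¹ for the SSP1/2/3/5-like scenarios)
  encode the qualitative scenario ordering — strongest natural-land loss
  under SSP3-RCP7.0, recovery under SSP1-RCP2.6 — not any global magnitude.
* **Climate** — daily Tmax per (cell, pseudo-GCM) = latitudinal mean
  gradient (10–34 °C across rows) + 8 °C sinusoidal season + AR(1) noise
  (lag-1 correlation 0.7, marginal s.d. 2.5 °C) + a small per-model offset +
  a linear warming ramp from 2015 at the scenario rate (0.10, 0.25, 0.35,
  0.55 °C/decade), i.e. up to ≈ 4.7 °C by 2100 under the SSP5-like scenario.
  Series are generated lazily per cell from independent child seeds, so
  memory stays bounded while results stay reproducible.
* **Species** — ranges grown as contiguous blobs by random accretion, sizes
  log-normal with smaller means for amphibians and reptiles; overlap
  fractions 0.15–1 on blob cells plus sub-threshold fringe cells that
  exercise the <10 % exclusion; habitat preferences drawn per class with
  forest and non-forest most likely; Red List labels drawn with
  LC-dominated frequencies.

What the generator does **not** emulate: real geography and coastlines,
spatially correlated weather between cells, humidity or physiological heat
stress, observed CMIP6 variance structures, or realistic co-occurrence of
habitat preference and land cover. Passing tests on these worlds therefore
validate the *pipeline logic and its invariants*, not any empirical global
magnitude.

### The null world

`make_null_world()` zeroes both trend families — but zero trends alone would
not make a clean negative control: with fresh stochastic weather, the
maximum over 81 future years would regularly beat the maximum over 56
baseline years, producing spurious "unsuitable" flags. The null world
therefore recycles the 1950–2005 noise block cyclically over the whole
1950–2100 span, so every future year replays a baseline year exactly. By
construction no future metric can exceed its baseline maximum, land use
never moves, and every species' percent change is identically zero — which
the acceptance-level test checks through the full pipeline, down to every
occupied cell landing in the neutral bivariate class.

## 7. Problem sizes, tolerances, degenerate inputs

The test and example worlds are 8×8 to 12×12 grids with 10–40 species and
3 pseudo-GCMs — chosen so the whole suite (≈ 2 800 assertions, including the
200-replicate ZOIB recovery and a 1 000-series brute-force oracle
comparison) completes in about a minute while still covering 151 × 365-day
series per cell and model; the generator's own defaults (30×30, 200
species) describe the intended desk-scale study size. Exact identities
(exposure 0.5 on the designed half-loss species, index bounds, extinction
idempotence) are asserted at 1e-9 or tighter; stochastic recovery checks use
the 3-standard-error convention. Degenerate inputs are contracts, not
crashes: empty overlap maps, missing baseline coverage, zero 2015 habitat
(species excluded and listed), even ensemble sizes, non-monotone bin edges
and out-of-range responses all raise typed errors; degenerate ZOIB layers
are flagged boundary fits.

## 8. Known limitations

* No dispersal, connectivity or population dynamics: exposure of the
  *current* range only, with instantaneous recolonisation — a deliberate
  best-case for land use.
* Binary climate suitability discards within-cell thermal heterogeneity and
  event timing within the year; a run crossing 31 December is split.
* The five-class habitat scheme is coarse; matching IUCN codes to LUH2
  states is partly judgement, which is why the mapping is an injectable
  configuration rather than a constant.
* The ZOIB model treats species as independent; phylogenetic or spatial
  random effects are out of scope.
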