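---
title: "Methods: land-use scenarios, green-space carbon and landscape risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: land-use scenarios, green-space carbon and landscape risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`greenrisk` chains five models that are usually run in separate GIS tools
into one reproducible R pipeline: Markov + constrained cellular-automaton
(CA) land-use projection, green-space evolution typing, four-pool carbon
bookkeeping, a grid-based landscape ecological risk index (ERI), and
coupling/bivariate-association statistics linking carbon change to risk
change. This vignette explains each model, the defaults, and the judgement
calls, in the package's own terms.

## The study system and its synthetic stand-in

The intended inputs are categorical land-cover rasters (six classes:
cultivated, forest, grassland, water, construction, unutilized; 1 km cells)
at two epochs, nine continuous driver surfaces, and a black-soil
conservation mask. Because no public rasters ship with the package, the
`synth_config()` / `generate_base_landscape()` / `evolve_landscape()` /
`generate_drivers()` family generates a study system with the statistical
structure the analysis assumes:

* **Categorical cover.** Gaussian white noise is smoothed with a Gaussian
  kernel (`autocorr_range_cells` = 6 cells by default, i.e. patches of
  roughly 10–20 km at 1 km cells) and thresholded at the empirical
  quantiles of the target class proportions. This guarantees class
  fractions close to the target and strong same-class adjacency, the two
  properties the patch metrics and the CA react to.
* **Default composition** (cultivated 0.35, forest 0.38, grassland 0.08,
  water 0.04, construction 0.09, unutilized 0.06) describes a
  cultivated/forest-dominated provincial landscape; it is a modelling
  default, not a calibration to any real province.
* **Ground-truth dynamics.** The second epoch is drawn cell-wise from a
  known row-stochastic transition matrix (`default_transition_matrix()`:
  strong persistence, modest cultivated/forest/grassland interchange,
  construction ratchet). Because the truth is known, transition
  estimation can be validated by parameter recovery: on a 300 × 300 grid
  every matrix entry is recovered within ±0.03 for rows with at least
  500 source cells (law of large numbers; the suite checks this).
* **Drivers.** Elevation is a two-scale random field (broad ranges plus
  rough texture) so the slope raster has a realistic tail above the
  15° policy threshold; slope comes from central finite differences.
  Temperature and precipitation are smooth fields; population and GDP are
  lognormal surfaces whose means are tripled inside a random "urban"
  disc so construction suitability has signal; road distances are exact
  Euclidean distance transforms of random polylines; the black-soil
  region is a contiguous disc sized by bisection to the requested area
  fraction.
* **What the generator does not emulate:** realistic topography or
  climate gradients, road network topology, spatially varying carbon
  density within a class, or any particular region's statistics. Passing
  tests therefore demonstrate correctness of the algorithms under known
  structure, not predictive skill on real landscapes.

All outputs are pure functions of `(config, seed)`; stage seeds are
derived from the master seed by fixed offsets, and the RNG state of the
caller is always restored.

## Markov demand and constrained CA allocation

`estimate_transition()` cross-tabulates the epochs into a transfer-area
matrix and row-normalises it; empty classes get identity rows. No matrix
root ("annualisation") is attempted: probabilities are per observation
period, and `project_class_areas()` raises the matrix to whole-period
powers only, because roots of empirical stochastic matrices need not
exist or stay stochastic. Fractional demands are rounded by largest
remainder so targets sum exactly to the valid-cell count.

`simulate_ca()` allocates demand over 10 iterations (5 × 5 neighbourhood
by default). Each iteration moves class counts a further 1/10 of the way
to target; growth classes claim candidate cells in descending
score order, score = suitability × neighbourhood density, with a seeded
10⁻⁹-scale jitter breaking ties reproducibly. Donor cells must belong to
classes currently above their scheduled count, and a conversion is only
ever made where the scenario's constraint mask permits it. When every
candidate inside an existing neighbourhood is exhausted, remaining
demand may seed new patches ranked by suitability alone — without this
fallback a class absent from a window could never expand there. If the
constraints make the demand infeasible the allocator reports the
shortfall in an attribute rather than violating a mask; this is the
designed behaviour under the conservation scenario, where conversion to
construction is prohibited on most of the map.

The multi-criteria (MCE) suitability layer min–max rescales each driver,
orients it per class (`default_suitability_orientations()`), combines
drivers with equal weights by default (none of the source material
prescribes weights; both weights and orientations are arguments), and
multiplies by the constraint mask. The two scenarios differ *only* in
their constraint masks: NP (natural progression) is unconstrained, BCU
(black-soil conservation and utilisation) encodes four rules — green
cells never convert to construction; cultivated cells are locked except
that cells steeper than 15° may convert to forest/grassland; no steep
cell may become cultivated; nothing converts to construction on the
black-soil mask. We read the policy's "trajectory" language as implying
no further difference between scenarios, since the transition structure
is estimated from the same historical pair.

Validation uses Cohen's kappa over valid cells (`kappa_agreement()`),
with the convention that two identical single-class maps score 1.

## Green-space evolution and carbon bookkeeping

Green space is the union of cultivated, forest, grassland and water;
construction and unutilized land are non-green. **Water counts as green**
under this four-type definition even though it is not vegetated — a
definitional choice inherited from the application domain and kept for
fidelity. Evolution types per cell: loss (green → non-green), expansion
(non-green → green), exchange (green → a *different* green class),
stable otherwise. The five labels partition the valid cells, and
swapping the epochs swaps expansion with loss while leaving exchange
invariant; both properties are asserted in the suite.

Carbon uses the classic four-pool accounting: a class's total density is
the exact sum of above-ground, below-ground, soil-organic and
dead-organic densities (t/ha), and a cell's stock is density × cell area
(100 ha for a 1 km cell). The bundled density table is a regional
estimate and deliberately swappable (`read_carbon_density()`), because
densities are the least transferable numbers in the whole chain. One
consequence worth knowing: water's total density (33.94 t/ha) is *below*
construction (42.08) and unutilized land (54.82), so a water → non-green
transition *gains* bookkept carbon even though it is a green-space loss;
the release property holds only for the three vegetated green classes.
Change maps difference the two epochs per cell and aggregate by
evolution type; the type-wise totals partition the overall change
exactly.

## Landscape ecological risk

The extent is tiled into square plots (default 20 km — two-to-five times
the mean patch size at the default autocorrelation; plots under 10%
valid data are dropped rather than padded, which avoids inflated
separation indices at ragged borders). Within each plot, patches are
8-connected components (the default of common landscape-metric
software), and for class *i* with patch count $n_i$ and area $A_i$:

$$C_i = n_i/A_i, \qquad
  S_i = \frac{A}{2A_i}\sqrt{\frac{n_i}{A}}, \qquad
  K_i = \frac{1}{4}\Big(\frac{n_i}{N} + \frac{m_i}{M}\Big) +
        \frac{1}{2}\frac{A_i}{A},$$

with $A$, $N$, $M$, $m_i$ grid-wide totals (total valid area, total
patches, plot count, plots containing class *i*) — the literal reading
of the index definitions. Disturbance is $I_i = 0.5C_i + 0.3S_i +
0.2K_i$; vulnerability $E_i$ is the rank normalisation (construction 1
… cultivated 6, each over the rank sum 21); the loss index is $R_i =
I_i E_i$, where we interpret the disturbance index as the "degree of
interference" factor in $R_i$ — the published formula references an
otherwise-undefined symbol at that point, and the disturbance index is
the standard choice in this index family. Plot risk is the area-weighted
sum $\mathrm{ERI} = \sum_i (A_i/A_n) R_i$.

Plot values are assigned to centroids and interpolated by ordinary
kriging: empirical semivariogram on 12 equal lag bins up to half the
maximum pairwise distance, spherical model fitted by weighted least
squares (weights $N_h/h^2$), exact at the data points when the nugget is
zero; duplicated centroids get a seeded micro-jitter; a singular system
falls back to inverse-distance weighting (power 2) with a warning.
Surfaces are banded into five classes either at the fixed reporting
thresholds (0.010 / 0.012 / 0.013 / 0.015 — meaningful only when ERI is
on the scale those thresholds assume) or, the pipeline default, by
Fisher–Jenks natural breaks. The Jenks optimiser is exact dynamic
programming; above 2000 values it first thins to 2000 order statistics,
which leaves break positions essentially unchanged for continuous
surfaces. Synthetic-landscape ERIs land roughly in 0.1–0.2, so the
pipeline's default banding is Jenks.

## Coupling coordination

With normalised subsystem values $W$ (carbon) and $S$ (risk):

$$C = 2\sqrt{\frac{WS}{(W+S)^2}}, \qquad T = \alpha W + \beta S, \qquad
  D = \sqrt{CT}, \qquad \alpha = \beta = 0.5 .$$

$C \in [0,1]$ with equality only at $W = S$; $D$ is monotone in both
arguments. Normalisation is min–max ("polar difference") over a pooled
set that the caller controls, because $D$ values are only comparable
within one pool: the pipeline pools per-plot green-space carbon and ERI
over all epochs/scenarios and then averages per period, which keeps the
period scores away from the degenerate 0/1 endpoints a three-point pool
would force. Risk enters in direct orientation by default (higher risk =
higher $S$); the inverse orientation is available but off, since the
published score table is reproducible only with the direct form.
Reported scores are rounded half-up at 3 decimals.

## Bivariate association of carbon change and risk change

Per-plot carbon change (by evolution stratum) and ERI change feed three
analyses:

* a Kolmogorov–Smirnov normality gate with the mean and SD estimated
  from the sample; since that invalidates the textbook K–S p-value, the
  p comes from a seeded Monte-Carlo null (the statistic is pivotal under
  the normal null, so the null table depends only on n and is reusable).
  The gate only decides whether Spearman is reported in place of
  Pearson; Spearman itself is the Pearson correlation of mid-ranks.
* bivariate global Moran's I, implemented verbatim as
  $I = n \sum_{ij} W_{ij} Q_{ki} Q_{lj} \big/ [(n-1)\sum_{ij} W_{ij}]$
  with population-SD z-scores; a `denominator = "geoda"` toggle computes
  the conventional cross-Moran form for cross-checking. Weights are
  queen contiguity on the plot lattice, row-standardised — the common
  default where only "adjacency" is specified. With row-standardised
  weights the local statistics satisfy $I = \sum_s I_s/(n-1)$, which the
  suite verifies numerically.
* LISA labels from a conditional permutation test: each unit's $Q_k$ is
  held fixed while its neighbours' $Q_l$ values are redrawn without
  replacement from the remaining units (999 draws by default, seeded);
  the two-sided pseudo p is $(\#\{|I^*|\ge|I_s|\}+1)/(n_{perm}+1)$, and
  significant units are labelled H–H / L–L / L–H / H–L by the quadrant
  of $(Q_k, \mathrm{lag}\,Q_l)$, others N–S. No multiple-testing
  correction is applied by design (matching standard practice for LISA
  maps); the empirical type-I rate on independent noise fields is close
  to α, which the suite checks at n = 400 over 20 seeds. Strata absent
  from a projection produce constant (all-zero) change vectors; the
  pipeline reports NA statistics for them instead of failing.

## Numerical choices and degenerate inputs

* Nodata cells (code 0) are frozen: excluded from counts, demands,
  metrics and statistics everywhere.
* Largest-remainder rounding is used wherever fractional class counts
  must become integers with a fixed total.
* Ties in CA scoring are broken by a seeded jitter nine orders of
  magnitude below the score scale.
* A class with proportion 1 yields a uniform map; identity transitions
  reproduce the input raster exactly; constant vectors are rejected by
  the normaliser, the K–S gate and Spearman with explicit errors.
* `coupling_degree(0, 0)` is undefined and returns 0 with a warning.

## Problem sizes

The test suite exercises full-size checks (parameter recovery and CA
calibration at 300 × 300; LISA level at 400 units × 999 permutations ×
20 seeds) and keeps everything else on 20–120-cell grids; the complete
suite and the end-to-end pipeline demo (80 × 80, two scenarios) run in a
few minutes on one core. These sizes are the package's validation
choices: the statistical contracts they check (±2 pp proportions, ±0.03
matrix recovery, ±1% CA calibration, α ± 0.03 LISA level) are stated at
exactly these sizes.

## Known limitations

* The CA allocation rule is a deterministic greedy scheme with seeded
  tie-breaks; it is auditable and reproducible but not a numerical
  replica of any proprietary implementation.
* Carbon density is constant within a class; no spatial variation or
  sequestration dynamics.
* The risk index family (fragmentation/separation/dominance) is one of
  several in use; the package implements this one exactly rather than a
  full landscape-metric suite.
* Kriging assumes second-order stationarity of plot ERI; strong trends
  are handled only as far as a large fitted range can absorb them.
* Scenario projections inherit every bias of the estimated transition
  matrix; with only two epochs there is no way to separate trend from
  noise in the transitions.
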