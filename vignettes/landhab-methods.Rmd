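---
title: "Models and methods in landhab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in landhab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landhab)
```

`landhab` implements the analysis chain used in long-term land-use /
habitat-quality monitoring of arid landscapes: change statistics between
classified land-use maps, landscape pattern metrics, an InVEST-style
habitat-quality model, variance-decomposition attribution of spatial
heterogeneity (the geographical detector), and a Markov + cellular
automaton simulator of future land use. This vignette states each model,
its assumptions, the tunable parameters and their defaults, the numerical
choices made where a published definition is ambiguous, and what the
synthetic-data generator does and does not establish.

## Raster conventions

All rasters in one analysis share a `grid_spec`: identical dimensions,
cell size (metres), origin and nodata sentinel. Storage is row-major with
the origin at the upper-left corner; distances are measured between cell
centres; areas are always reported in km² regardless of cell units, with
the conversion explicit (`cell_size²/10⁶`). Nodata cells are excluded from
every statistic, metric and model — the only self-consistent choice when a
source does not specify the treatment. I/O is the plain-text ESRI ASCII
grid, which round-trips integer class codes exactly; no binary geospatial
library is required (or available in the supported environment), so
GeoTIFF input is refused with an informative error rather than silently
misread.

The Euclidean distance transform uses the exact two-pass separable
lower-envelope algorithm on squared distances, so it agrees with the
brute-force all-pairs minimum to floating-point precision (property-tested
on all small grids).

## Land-use change statistics

The dynamic degree `K = ((U_b − U_a)/U_a)(1/T)·100` is undefined at
`U_a = 0` and is signalled as an error, never returned as infinity. The
comprehensive dynamic degree divides the *gross* off-diagonal transfer
area (halved) by total start-date area: the net-change reading cannot
reproduce published comprehensive dynamics, so the transfer matrix is a
required input. Period length `T` is a caller-supplied parameter: decadal
monitoring intervals are rarely exact decades, and the reference tables
this package is tested against are internally consistent only with `T = 9`
for a nominal 1991–2000 period and `T = 10` for the following two decades.
The multi-decade 1991–2019 column of those tables is consistent with no
single `T` and is carried as data but excluded from numeric checks.

Display rounding (2 decimals, half away from zero, `round_half_up()`) is
applied only at report time; all computation is double precision.

## Landscape pattern metrics

Patches are maximal connected sets of same-class cells, 8-neighbour by
default (4-neighbour available); all adjacency counts are rook
(4-neighbour). This split — queen patches, rook adjacencies — is the
de-facto convention of raster landscape-metric software. Further
conventions, each of which must be fixed for the numbers to be
well-defined:

* **Perimeter** counts cell edges facing a different class, nodata, or the
  landscape boundary; boundary edges count toward perimeter but never
  toward adjacencies.
* **LSI** divides class edge by the perimeter of the integer-sided
  quasi-square of the same cell count (`4n`, `4n+2`, or `4n+4` for
  `a = n²`, `a ≤ n(n+1)`, larger).
* **AI** divides the single-count like-adjacency count by that of the
  maximally clumped quasi-square arrangement; it is undefined (NA) for a
  single-cell class, and the landscape AI is the class-proportion-weighted
  mean over classes where it is defined.
* **CONTAG** follows the standard published contagion definition with the
  double-count adjacency convention; it requires at least two classes.
  Note that contagion is *not* minimised by a checkerboard: it measures
  distance of the adjacency mix from uniform, so an all-unlike pattern
  scores 50 (two classes), while a 50/50 like/unlike mix scores 0. The
  test suite encodes this with a monotone halves → width-2 stripes →
  width-1 stripes sequence.
* **PD** is reported per km²; published tables sometimes print other area
  units, but nothing downstream depends on the choice.

Every metric is verified against an independent definitional oracle
(naive loops in the test helpers) on hundreds of seeded random grids.

## Habitat quality

Degradation at cell `x` of class `j` is the weight-normalised,
sensitivity-scaled sum of decayed threat influences,

\[ D_x = \sum_r \sum_y \frac{w_r}{\sum_r w_r}\; r_y\; i_{rxy}\; \beta_x\; S_{jr}, \]

with `i_rxy` either linear (`1 − d/d_max`) or exponential
(`exp(−2.99 d / d_max)`), both truncated to zero beyond `d_max`. Truncation
at `d_max` (rather than letting the exponential tail run) makes the kernel
bounded, so the production path (FFT convolution of the threat indicator
with the kernel) and a brute-force double loop are *the same sum* and agree
to ~1e−12; the test suite asserts 1e−10 on 12×12 grids over 100 seeds.
Threat intensity `r_y` is the 0/1 class indicator (no density data),
and the accessibility/protection factor `β` defaults to 1 everywhere.

Quality is `Q = H_j (1 − D^z/(D^z + k^z))`. The `z` exponent defaults to
2.5 (the conventional model default). Because the degradation formula
*sums* rather than averages over threat cells, the absolute scale of `D`
grows with threat density and map extent: at 30 m resolution with
kilometre-scale threat radii a fixed `k = 0.5` drives `Q` to ≈0 everywhere.
The functions therefore default to `k = 0.5` for contract fidelity, but
accept `k = "half-max"` (half the maximum observed degradation), which the
pipeline uses by default so the quality surface stays informative whatever
the threat density. Absolute quality values are thus configuration-
dependent; only orderings, classings and changes should be compared across
runs with the same configuration.

Default threat parameters (weights, maximum distances in km, decay modes)
and the habitat-suitability / sensitivity table ship as
`threat_table()` / `sensitivity_table()` and as CSVs under `inst/extdata/`:
forest grassland is the reference habitat (H = 1), construction land the
strongest threat (weight 0.9, 8 km, exponential).

Classification uses five equal intervals on [0, 1], left-closed,
right-open, with the top bin closed. Change classing uses the thresholds
obvious improvement (> 0.5), slight improvement (0, 0.5], invariable
(exactly 0), slight degeneration [−0.5, 0), severe degeneration (< −0.5);
ties at ±0.5 deliberately fall into the *slight* categories because the
published bands are printed closed on the slight side.

## Geographical detector

The q-statistic uses population variances so that `q = 1 − SSW/SST`
exactly; cells are the sampling units, with no spatial thinning (the
choice is documented so results are reproducible, but it means the
permutation p-values ignore spatial autocorrelation — see Limitations).
Significance is assessed by permuting stratum labels (default 999
shuffles) rather than a noncentral-F approximation: permutation is
assumption-free and directly testable. Continuous drivers are discretised
by Jenks natural breaks (default 7 grades), computed by the exact Fisher
dynamic program on the weighted distinct values; above 2048 distinct
values the program runs on a 2048-point quantile support grid (a standard
large-n approximation whose effect is far below the granularity of a
7-class grading). Categorical layers pass through `as_strata()` untouched.
The interaction detector overlays two stratifications as their
cross-product and classifies `q12` against `q1`, `q2` with the standard
nonlinear/single-factor weaken, bivariate/nonlinear enhance, independent
taxonomy.

## Land-use simulation

Demand comes from a Markov projection of current class areas through the
row-stochastic transition matrix estimated from the two calibration dates
(`transfer_matrix(...)$prob`); empty classes are frozen rather than
renormalised. Expansion probability is learned per class from cells that
*gained* the class between the calibration dates (positives) versus a
matched random sample of non-gain cells, on the driver stack. The
classifier is a pluggable `fit`/`predict_prob` contract; the default is
binomial logistic regression, chosen because the supported environment
provides no decision-tree ensemble and a linear-logit learner recovers
monotone driver rules well (the tree-ensemble default of the reference
methodology can be plugged in unchanged where available).

The cellular automaton converts cells of surplus classes (current count
above target) into deficit classes. Each round, a candidate cell's score
for gaining class `g` is `suitability × (w_g × neighbourhood share +
seed)`, where the neighbourhood share is the fraction of `g` among the
eight Moore neighbours, `w_g` a per-class weight (default 1), and `seed` a
per-cell Bernoulli indicator (default probability 0.01) that lets new
patches nucleate away from existing ones. A cell converts when its best
score beats a decreasing random threshold (initial 0.8, ×0.9 per round),
the gaining class drawn roulette-wheel over scores; conversions are
applied strongest-first and capped by the remaining per-class demand and
by donor surplus, so total area is conserved *exactly* and forbidden
transitions (a class×class permission matrix) never occur. All randomness
derives from the configured seed; reruns are bit-identical. If the
permission matrix makes demand unreachable the allocation stops at the
round cap and reports the unmet cell count. An optional `trans_weight`
matrix (typically the calibrated transition probabilities) can multiply
the (from, to) score so donor composition follows the observed gross
flows; it is off by default.

Validation offers Cohen's kappa on the cellwise confusion matrix and the
figure of merit `B/(A+B+C+D)` over the change sets (missed change, correct
change, wrong-class change, false alarms).

## The synthetic world

`synth_scenario()` describes a fully seeded artificial study area built to
emulate the inputs of a desert re-greening analysis: six land classes on a
30 m grid (200×200 cells at desk scale), spatially autocorrelated smooth
fields for terrain, climate and socio-economic surfaces (slope derived
from the synthetic DEM, temperature negatively coupled to it, GDP
following population, population decaying away from settlements), exact
distance fields from seeded line/point features, and a ground-truth
decadal Markov matrix in which sandy land converts mainly to forest
grassland while cultivated and construction land expand slowly. Class
intercepts are set so the initial composition echoes the reference world:
sandy ≈ 45 %, forest grassland ≈ 35–40 %, cultivated and water a few
percent each, construction and unused rare.

Conversion placement is the one free choice that decides whether
end-to-end simulator recovery is even possible. Each step converts, for
every ordered class pair, `round(N_m P[m,n])` cells — so the empirical
transfer matrix recovers the ground truth almost exactly — and chooses
*which* cells convert by ranking the donor class's cells on the gaining
class's driver score plus Gumbel noise (sd 0.2). At that noise level the
realised conversions overlap an oracle score ranking by roughly 70 %;
with substantially larger siting noise (e.g. sd 0.5, oracle overlap
≈ 50 %) *no* allocator — not even one ranking by the true score — can
place enough change correctly to beat the persistence baseline on kappa,
because every misplaced change cell costs the simulation twice. The
generator therefore encodes a world where conversion siting is
predominantly driver-determined, which is precisely the regime in which
expansion-learning simulators are the right tool. A green recovery test
establishes that the chain (transfer estimation → expansion learning →
demand projection → CA allocation) recovers a *recoverable* world; it does
not establish that real landscapes are this predictable.

What the generator does **not** emulate: classification error in the input
maps, within-class threat-intensity variation, policy shocks that break
Markov stationarity, anisotropic or long-range spatial structure, and
real distance-field geometry (features are random walks and points).
Conclusions from green tests transfer to real data only insofar as those
features do not dominate.

## Numerical choices, in one place

* FFT convolution is used for threat kernels and neighbourhood shares;
  agreement with direct loops is asserted at 1e−10 in tests, and negative
  FFT ringing at exact zeros is clipped.
* Exact Euclidean distance transform (lower-envelope); no raster
  approximation (chamfer etc.).
* Equal-interval bin edges are left-closed; the top bin is closed; change
  classing assigns ±0.5 ties to the slight categories; ΔQ must be exactly
  0 to be invariable.
* Markov demand is converted to integer cell targets by largest-remainder
  rounding, so targets sum exactly to the landscape cell count (the ≤ 1
  cell mismatch the published tables tolerate is absorbed here).
* Jenks ties resolve to the first optimal split; permutation p-values use
  the add-one estimator `(b+1)/(B+1)`.
* Display rounding is half-away-from-zero, applied only when printing.

## Limitations

* Absolute habitat-quality values depend on the half-saturation choice;
  the authors of the reference methodology do not publish theirs, so only
  internal comparisons are meaningful.
* The geodetector permutation test treats cells as exchangeable; under
  strong spatial autocorrelation its p-values are anti-conservative.
* The CA has no multi-scenario constraint machinery (ecological redlines,
  planning masks) beyond the transition-permission matrix.
* The expansion learner's default logistic model is linear in the logit;
  strongly non-monotone driver responses need a plugged-in classifier.
* GeoTIFF is not read; convert to ESRI ASCII grid first.
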