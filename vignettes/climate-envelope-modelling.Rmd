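---
title: "Climate-envelope suitability modelling with ecosuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climate-envelope suitability modelling with ecosuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecosuit)
```

## The model

`ecosuit` implements a GMPGIS-style climate-envelope model: a species
is predicted to grow wherever every ecological factor lies within the
range the species is observed to tolerate, and where the soil class is
one it is observed on. The pipeline has four stages.

**1. Linear normalization.** Each climate layer $A$ is rescaled to a
common 0–100 scale from its own valid-cell extremes,

$$v' = \frac{v - \min_A}{\max_A - \min_A} \times 100,$$

so that variables with very different units (millimetres of rain,
degrees, W m^-2^) contribute comparably to distances. The statistics
come from the *layers*, not from the occurrences: an occurrence value
outside the layer range (possible when layers are cropped)
extrapolates linearly rather than being clipped. Constant layers are
rejected at fit time.

**2. Range-based clustering.** Occurrence climate points are grouped
by an improved k-means in which a cluster is represented not by a
centroid but by its *scope* $d_i$ — the per-variable
$[\min, \max]$ hyper-rectangle over its members. The distance from a
point $p$ to a scope is zero for every variable inside the range and
the distance to the nearer bound otherwise, aggregated as a Euclidean
norm; the objective is

$$E = \sum_{i=1}^{k} \sum_{p \in D_i} \mathrm{dist}(p, d_i)^2 .$$

A structural property of this objective deserves stating plainly:
because every member of a cluster lies inside its own bounding box,
$E = 0$ for *every* partition once scopes are recomputed from members.
$E$ therefore certifies convergence (the package asserts the reported
$E$ against a brute-force recomputation) but cannot rank converged
partitions. `fit_clusters()` consequently selects among random
restarts lexicographically by $(E, \text{total squared scope width})$:
among zero-objective solutions it keeps the tightest boxes. That
secondary criterion is what makes the two-blob example resolve the way
one expects, and the exhaustive-enumeration oracle in the tests uses
the same rule. Assignment ties go to the lowest cluster index; a
cluster that empties during iteration is re-seeded from the point
farthest from its assigned scope. The default is $k = 1$, which
reproduces a classic single per-species range table (the published
table format); multi-cluster mode exists because the objective
explicitly sums over clusters, and is useful for disjunct
distributions.

**3. Envelope distance and suitability.** Every valid cell of the
layer stack gets the range distance (normalized units) to the nearest
cluster scope. The bounded suitability index is

$$s = 0.999 \, e^{-D/\sigma},$$

with $\sigma$ the median positive distance over valid cells (fallback
1 when every cell is inside the envelope), so $s = 0.999$ — best
habitat — exactly at $D = 0$ and $s \to 0$ as $D$ grows. The exact
form of this map is a presentation choice: only its endpoints are
fixed by the modelling convention, and nothing downstream depends on
it, because the binary suitable mask that drives all area accounting
is threshold-free — a cell is suitable iff $D = 0$ *and* its soil
class is in the profile's allowed set (the classes observed at
occurrence cells). Cells on disallowed soil get $s = 0$. With
$k = 1$ the mask provably equals the classic rectangular-envelope
(BIOCLIM-style) inclusion test; the suite asserts that equivalence.

**4. Area accounting.** All computation stays in geographic
coordinates (WGS84). Rather than projecting to a zone-local system,
suitable areas use the exact spherical area of each grid row,

$$A = R^2 \, \Delta\lambda \, (\sin\varphi_N - \sin\varphi_S), \qquad
R = 6371.0088\ \mathrm{km},$$

which integrates to $4\pi R^2$ over the globe to machine precision.
Cells are attributed to the administrative region containing their
center (point-in-polygon); this matches raster-overlay practice at
arc-minute resolutions but is a known source of boundary error
relative to area-weighted clipping — the refinement test bounds it at
under 2% when the cell size halves. Suitable cell centers in no
region (ocean) are reported in an explicit `unassigned` row, so a
species' global total equals continents plus unassigned exactly.
Areas are reported in km² and in the conventional
$\times 10^5$ km² unit.

## Jackknife variable importance

To rank the factors constraining a species' distribution, occurrences
are split 75/25 (seeded shuffle; sizes `round(n * f)` and the
residual), and for each variable $v$ two envelope models are fitted
on the training rows: with only $v$, and with all variables except
$v$.

Scoring needed a design decision. The obvious score — the fraction of
held-out occurrences inside the fitted envelope — cannot rank
variables: removing a variable only relaxes an envelope, so the
without-$v$ score never drops, and for continuous data the chance
that a held-out point escapes a training range of $m$ samples is
$2/(m+1)$ *regardless of the variable*. Each model is therefore
scored as

$$\text{score} = \text{test inclusion rate} - \text{scene coverage},$$

where coverage is the fraction of the landscape's valid cells the
envelope admits — a lean presence-versus-background analogue of the
gain statistic used by maximum-entropy software (whose model itself
is out of scope here). An uninformative variable spans the landscape
and earns nothing; a constraining variable buys a small envelope at
little cost in held-out inclusion. The contribution of $v$ is
$\max(0, \text{score(all)} - \text{score(without } v))$, floored at
zero because sampling noise can produce small negative differences,
and normalized to sum to 100. Raw inclusion and coverage components
are reported alongside. When no variable lowers the score — for
example when every variable is duplicated by a collinear twin —
contributions fall back to uniform with a warning rather than
dividing by zero. A variable constant on the training rows
contributes zero, with a warning.

## The virtual-species generator

Synthetic scenes stand in for the global occurrence/climate/soil
downloads a real analysis would use, with a fully known truth:

* **Climate** — six factors (annual mean, warmest- and
  coldest-quarter temperature; annual precipitation, radiation,
  relative humidity) as linear spatial gradients plus optional
  independent Gaussian cell noise. By default the temperature
  variables run west–east and the moisture/radiation variables
  south–north, so the footprint of any value envelope is an
  analytically locatable rectangle. The default ranges are realistic
  for a temperate-to-subtropical window (e.g. radiation
  100–170 W m^-2^, precipitation 0–3000 mm).
* **Truth** — a `true_envelope()` of per-variable intervals plus an
  allowed soil-class set; the default mirrors a published envelope of
  a temperate *Dioscorea* yam. Multi-component (disjoint) niches are
  supported.
* **Soil** — a seeded Voronoi mosaic in which each of the (default 8)
  classes owns three patches, the way soil classes recur across a
  landscape. A single patch per class would leave the niche rectangle
  entirely on disallowed soil for a nontrivial fraction of seeds;
  with recurring patches a valid scene is the overwhelming rule, and
  callers that sweep seeds simply advance to the next seed on the
  explicit "empty niche" error (which names the most restrictive
  variable, or soil).
* **Occurrences** — `n` records at centers of cells inside the truth
  (climate and soil), sampled with replacement; a `detection_noise`
  fraction is re-sampled uniformly over the whole grid as a simple
  mis-georeferencing model. Defaults are noise-free: the recovery
  guarantees the tests state (fitted envelope nested in the truth,
  mask equal to the truth footprint) are exact only in that regime.
* **Regions** — a 2 × 2 block of rectangular countries in two
  continents, sufficient to exercise point-in-polygon attribution,
  aggregation and the unassigned row.

Everything is a pure function of one integer seed. What passing tests
on these scenes do *not* show: behaviour under spatially
autocorrelated sampling bias, interpolation artefacts in real
climate surfaces, or realistic climate physics — the generator makes
no attempt at any of these.

## Phylogenetics component

The species-relationship module consumes an already-aligned FASTA
(concatenated chloroplast markers such as *matK* + *rbcL* are the
intended use) and computes Kimura 2-parameter distances,

$$d = -\tfrac{1}{2} \ln\!\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right],$$

with $P$ and $Q$ the transition and transversion proportions. Sites
with gaps or ambiguity codes are excluded *pairwise* (the common
default; complete deletion would discard whole columns), and
saturation ($1 - 2P - Q \le 0$ or $1 - 2Q \le 0$) is an explicit
error. Trees are built by standard neighbor-joining with the
Q-criterion and Studier–Keppler updates; ties in Q break toward the
pair containing the lowest original taxon indices, and negative
intermediate branch lengths are clamped to zero with the deficit
moved to the sister edge. Bootstrap supports resample alignment
columns with replacement and score each internal edge of the
full-data tree by bipartition identity (canonical split keys anchored
at the lexicographically smallest taxon, so keys are independent of
input order and rooting); replicates that hit saturation are dropped
and counted, and percentages are over the retained replicates. The
test suite cross-checks distances against an independent
implementation and verifies exact recovery of additive matrices.

The companion simulator evolves sequences along any tree under the
exact closed-form two-parameter transition probabilities, with branch
lengths in expected substitutions per site, so the expected K2P
distance between two leaves equals their path length — making
distance estimation, topology recovery and bootstrap behaviour all
testable against a known truth.

## Numerical choices and problem sizes

* Grid co-registration is exact to 1e-9 degrees; cell ownership is
  half-open (a point on a shared edge belongs to the cell to its
  south-east).
* Normalized-scale computations are plain doubles; the objective
  consistency checks use a 1e-9 tolerance.
* Restarts default to 10 with seeds `seed + 0 … 9`; iteration caps at
  100 with a 1e-9 objective tolerance.
* The test and acceptance workloads use 40 × 40 scenes with 120–200
  occurrences, 20-replicate oracle sweeps, 5000-site alignments for
  topology recovery and 200 bootstrap replicates — sizes chosen so
  the whole suite runs in well under a minute per module while
  leaving the statistical margins (e.g. ≥ 19/20 recovery) wide.

## Known limitations

* The envelope is rectangular per cluster; correlations between
  variables are only captured through multiple clusters, not through
  oblique envelope shapes.
* Presence-only inclusion is a weak signal for importance ranking at
  small test sizes; the coverage-penalized score mitigates but does
  not remove this.
* Cell-center region attribution misassigns boundary-straddling
  cells; at coarse grids with small countries the per-country error
  can exceed the global one.
* The suitability index between its endpoints is a convention, not a
  probability; only the binary mask carries quantitative meaning.
* No reprojection or resampling: all rasters must arrive
  co-registered, and only geographic (lon/lat, WGS84) grids are
  supported.
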