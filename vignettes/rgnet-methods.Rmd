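---
title: "Quantifying reactive glial nets: models, parameters and design choices"
author: "rgnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying reactive glial nets: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgnet)
```

## The measurement problem

In Alzheimer's disease, activated microglia and reactive astrocytes organize
into a stereotyped three-dimensional structure around beta-amyloid plaques: an
inner shell of amoeboid Iba1+ microglia hugging the plaque core, and an outer
corona of hypertrophic GFAP+ astrocytes — a *reactive glial net* (RGN). The
quantitative signature of this structure, as measured in post-mortem tissue,
consists of:

* **Radial positioning.** Around dense-core plaques, microglial somata
  concentrate roughly 20–30 µm from the plaque center and astrocyte somata
  30–50 µm out, with astrocyte reactivity essentially complete by 80 µm. In a
  transgenic mouse time course, the astrocyte shell sits near 40 µm at
  mid-stage disease and near 60 µm at late stage.
* **The interval-max-GFAP statistic.** For each plaque, radial distances from
  the plaque center are binned; the bin containing the maximum number of
  GFAP+ somata defines the net, and its outer edge is the net boundary.
  Microglia within that boundary are *intra-RGN*.
* **Recruitment correlations.** Across a plaque cohort, the Pearson
  correlation between glial counts (total Iba1+, intra-RGN Iba1+, GFAP+) and
  plaque volume summarizes volume-dependent recruitment. Fibrillar plaques
  recruit roughly twice as many microglia as dense-core plaques at matched
  net boundaries; PHF/NFT aggregates show no microglial recruitment at all.
* **Territory maps.** In 2D maximum-intensity projections, Voronoi
  tessellation of microglial somata and nearest-neighbor distances expose
  aggregation near plaques and depletion in adjacent zones.

The tissue images behind those observations are not publicly available, so
the package pairs every measurement with a seeded synthetic generator whose
ground truth is recorded. Every stage — generation, rendering, detection,
profiling, tessellation, statistics — is exercised end to end in the test
suite.

## The generative model

`makePreset()` returns the generative parameters for one condition. A plaque
of volume $V$ (µm³) sits at the center of a cubic field (default
220 µm side, large enough to hold the 100 µm analysis radius), with
equivalent radius $r_\mathrm{eq} = (3V/4\pi)^{1/3}$.

**Radial law.** Shell somata sit at distances $r$ drawn from a normal
distribution with marker-specific mean and sd, truncated below at
$\max(r_\mathrm{core}, r_\mathrm{eq})$ and — for astrocytes — above at
`astroMaxUm`; directions are uniform on the sphere. A truncated normal is the
simplest two-parameter family consistent with "centered about X µm"
statements; sampling uses exact inverse-CDF inversion, so no rejection loop
and full determinism per seed.

**Count model.** Shell counts are
$N = \mathrm{round}(\beta_0 + \beta_1 V + \varepsilon)$,
$\varepsilon \sim N(0, \sigma)$, clamped at zero with a warning. Given a
target population correlation $\rho$ between count and volume, $\sigma$
follows in closed form:
$\sigma = \beta_1\,\mathrm{sd}(V)\sqrt{1/\rho^2 - 1}$,
with $\mathrm{sd}(V)$ the analytic sd of the log-uniform volume law (volumes
span orders of magnitude in tissue and no distribution is reported, so
log-uniform over a configurable range, default 500–20 000 µm³, is used).
When a recruitment slope is zero the correlation target is vacuous and
Poisson-like $\sqrt{\beta_0}$ count noise is used instead. Rounding,
clamping and background cells perturb the realized correlation by well under
the ±0.05 band checked in the tests.

**Presets.** The five built-in conditions differ as follows (all shells in
µm; see `makePreset()` for every default):

| preset | astro shell | microglia base/slope | target r (iba1) |
|---|---|---|---|
| human-dense-core | 40 (sd 6, max 80) | 12 / 8e-4 | 0.45 |
| human-fibrillar  | 40 (sd 6, max 80) | 24 / 1.6e-3 | 0.561 |
| human-phf-nft    | 40 (sd 6, max 80) | 3 / 0 | 0 |
| mouse-mid        | 40 (sd 6, max 80) | 15 / 8e-4 | 0.264 |
| mouse-late       | 60 (sd 6, max 100) | 20 / 1.2e-3 | 0.264 |

Three of these numbers are package choices rather than reported values, made
once and documented here:

* The fibrillar condition doubles both the microglial base count *and* the
  recruitment slope. Doubling only the base would not double the total count
  (the volume term would dilute the ratio); the doubling statement concerns
  detected totals, and the package treats it that way.
* The human dense-core population correlation for Iba1 is not printed in the
  source observations (only "positive correlation"); 0.45 is used, below the
  fibrillar 0.561 to preserve the reported ordering. The mouse late-stage
  correlations reuse the mid-stage values for the same reason. The GFAP
  target (0.479) is shared by both human amyloid conditions because astro
  behaviour is reported as preserved across subtypes.
* Background (non-net) glial density is nowhere stated; 1000 cells/mm³ per
  marker is used — sparse relative to total glial density in cortex, which
  is appropriate because background here means *reactive* (marker-bright)
  somata unrelated to the net, not all glia. At this density a 10 µm outer
  radial bin collects ≈1 background cell, far below shell peak counts, so
  the interval-max statistic is not perturbed.

**Seeding.** `generateCohort()` consumes one master seed: volumes are drawn
first, then one sub-seed per plaque is drawn from the master stream, so any
single plaque can be regenerated in isolation (`sampleGlia(plaque, preset,
seed = gt$plaque_seeds[k])`). The pipeline orchestrator derives stage seeds
from its master seed by fixed documented offsets for the same reason.

**Landscapes.** For the 2D territory analysis, `generateLandscape()` draws
uniform somata in a 1 mm² ROI; in plaque-perturbed mode a stated fraction of
the somata falling in the annulus between the aggregation radius and the
depletion radius around a plaque is relocated uniformly into the aggregation
discs. Starting from the identical uniform draw makes
`aggregationFraction = 0` reproduce the homogeneous pattern exactly under
the same seed — a property the tests pin down.

## Rendering and detection

`renderStack()` rasterizes a field into a 3-channel stack (iba1, gfap,
plaque) at a default voxel size of 0.5 × 0.5 × 1 µm — the anisotropy of a
confocal stack with a 1 µm z-step. Somata are isotropic Gaussian blobs
(σ = 1.5 µm, amplitude 1); dense-core plaques are filled spheres of the
equivalent radius, fibrillar plaques annular shells (inner radius half the
equivalent radius), the package's reading of a core-less fibril mass.
Voxel $(i,j,k)$ (1-based) spans the half-open box starting at
$((i-1)\Delta_x, \dots)$, so a voxel's center is at $(i-\tfrac12)\Delta$.

Detection is deterministic given the stack: thresholding (Otsu's 256-bin
between-class-variance maximizer, or a fixed cutoff), 26-connected component
labeling (8-connected in a single slice) via an explicit voxel-adjacency
graph resolved with igraph, a minimum component volume of 8 µm³ (well below
soma volume, rejects noise specks; configurable), and unweighted binary
centroids. Binary rather than intensity-weighted centroids mirror manual
soma marking, and the choice is isolated so it can be flipped. There is no
watershed: touching somata merge into one component, an acknowledged
limitation — the recovery guarantees in the tests hold for blobs separated
by more than 4σ.

## Profiling and statistics

`profilePlaque()` measures distances to the plaque *center* (not surface;
the generator's core-radius truncation keeps this meaningful), bins them in
half-open 10 µm bins (every reported shell position sits on a 10 µm grid;
configurable), and takes the GFAP argmax bin. Three conventions are
deliberate and fixed:

* The outermost bin is closed above, so a distance equal to the maximum
  radius (default 100 µm — the 80 µm completion distance plus margin) is
  still counted; conservation is tested.
* Ties in the argmax break toward the innermost bin: conservative (smaller
  net) and deterministic.
* The net boundary is the *outer* edge of the argmax bin — the inclusive
  reading of "the interval defines the limit".

A plaque with zero GFAP+ cells inside the maximum radius has no defined net;
its profile is flagged and excluded from cohort statistics rather than
silently contributing zeros, which would bias the correlations. Per-plaque
argmax is computed first and averaged across plaques afterwards (the
per-plaque statistic is what defines each net; the alternative — averaging
histograms before the argmax — would hide inter-plaque variability).
Distances are 3D throughout: the data these methods model are z-stacks
analysed volumetrically.

The statistics module implements exactly the named tests: Pearson r, one-way
ANOVA on the plaque factor, Tukey–Kramer post hoc with the studentized range
distribution (the Kramer harmonic term reduces algebraically to the classic
Tukey term at equal sizes — tested), and two-sided Student t tests with
pooled variance (pooled, not Welch, because the classic Student test is what
is named). The post hoc runs when the ANOVA rejects at 0.05 and there are
more than two groups — "when appropriate" is otherwise undefined. Type-I
error of the ANOVA and t test is verified by simulation (10 000 null
replicates, 0.05 ± 0.01), along with the $F = t^2$ identity on two groups.

## Voronoi territories

`tessellate()` builds each seed's Voronoi cell directly, by clipping the ROI
rectangle with perpendicular-bisector half-planes against the other seeds,
nearest first, stopping when no farther seed can cut the running polygon
(a seed farther than twice the current circumradius cannot contribute).
The construction is exact for the clipped diagram, and the clipped areas of
all cells partition the ROI — the suite checks conservation to a relative
1e-6 on random instances. Cells whose polygon touches the ROI boundary are
*incomplete*: their unclipped territory extends beyond the observed region,
so they are excluded from area statistics (only complete cells are
area-coded), while still participating in the partition. Duplicate seeds
(identical centroids from clumped detection) merge with a warning, since
they would otherwise degenerate the diagram. The analysis is strictly 2D on
maximum projections; no 3D Voronoi is attempted.

## What the synthetic data does and does not show

The generator emulates: the three plaque classes and their distinct
recruitment regimes, shell geometry with truncation, volume-dependent counts
calibrated to population correlations, background somata, stage presets for
the mouse time course, and aggregation/depletion landscapes. Passing tests
therefore demonstrate that the *pipeline recovers known ground truth under
the stated geometric model* — shell positions within half a bin, count
correlations within ±0.05, twofold microglial contrast within ±0.2,
detection of well-separated somata with sub-voxel centroid error.

They do not demonstrate performance on real tissue: true somata are not
Gaussian blobs and clump; real radial distributions need not be symmetric
truncated normals (an astrocyte corona with a heavy outer tail would push
per-plaque maximum distances toward the 80 µm completion bound, where this
generator's sd-6 shell keeps per-plaque maxima near 53 µm); plaque
segmentation in tissue contends with autofluorescence the renderer does not
model; and manual soma marking has operator variance with no analogue here.
Detection parameters (threshold method, minimum volume) are this package's
own and must be tuned per dataset.

## Problem sizes and numerical choices

The test suite and acceptance script use cohorts of 100 plaques for shell
recovery, 200 per arm for the fibrillar contrast, and 2000 for correlation
calibration — sizes at which the sampling error of each statistic is
comfortably below the band being checked (for example, the se of a Pearson r
near 0.56 at n = 2000 is about 0.015 against a ±0.05 band). Tessellation
oracle checks run on 100 random instances of up to 200 seeds. Type-I error
uses 10 000 null replicates (binomial se ≈ 0.002 against ±0.01). All
stochastic stages consume explicit integer seeds; repeated runs are
byte-identical, which the suite asserts.

## Known limitations

* No splitting of touching somata; detection undercounts in dense clusters.
* Somata only — no processes, so morphology-based classification
  (amoeboid vs ramified) is out of scope, as is any reconstruction of
  astrocyte process invasion into fibrillar plaques (the presets move
  counts, not astrocyte shell geometry, matching the reported preservation
  of astrocyte distances across plaque subtypes).
* The count model is linear in volume with additive Gaussian noise; real
  recruitment may saturate.
* TIFF metadata (channel names, voxel size, intensity scale) travels in a
  JSON sidecar next to the image, not in TIFF tags.
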