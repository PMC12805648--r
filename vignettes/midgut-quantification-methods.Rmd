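---
title: "Quantifying Drosophila midgut cell populations from 3D confocal stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Drosophila midgut cell populations from 3D confocal stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(midgutcyto)
library(dplyr)
```

## The quantification problem

The adult *Drosophila* posterior midgut is maintained by intestinal stem
cells (ISCs) that divide and differentiate into absorptive enterocytes (via
enteroblasts) or secretory enteroendocrine (EE) cells (via EE progenitors,
EEPs). Experiments on this lineage are read out almost entirely through
multichannel confocal z-stacks: every nucleus carries DAPI; ISCs and
progenitors express an Escargot (Esg) reporter that fills the cytoplasm; EE
cells and their progenitors carry nuclear Prospero (Pros); lineage-tracing
(ReDDM) adds a stable nuclear RFP inherited by differentiated progeny;
Ref(2)P (the fly p62) forms cytoplasmic puncta when autophagic flux is
blocked; and 10XSTAT-GFP reports JAK-STAT activity as graded fluorescence.

`midgutcyto` turns such stacks into per-gut tables: counts and percentages
of each population, puncta per cell, and normalized reporter intensity,
followed by the statistical layer used for figure panels (normality-gated
test selection, Dunnett/Dunn post-hocs, Kaplan-Meier survival with the
Mantel-Cox log-rank test, and 2^-ddCt relative expression). Because no raw
imaging data are publicly available for this assay family, the package
includes a seeded synthetic-scene generator with exact ground truth; all
quantitative claims made by the test suite are claims about recovery of
planted truth, recomputed at run time.

## Image model and physical units

Every operation works in micrometres and converts to voxels per axis using
the stack's voxel sizes, so anisotropic acquisitions (e.g. 0.4 um pixels
with 1-2 um z-steps) are handled transparently. Voxel `i` along an axis of
pitch `d` has its centre at `(i - 0.5) * d`; spot coordinates are reported
in this physical frame, never in voxel indices.

Preprocessing reproduces the standard conditioning sequence:

* `gaussian_smooth(stack, ch, sigma_um = 0.6)` — noise suppression. The
  0.6 um scale is interpreted as the Gaussian **sigma** (not FWHM); this is
  configurable.
* `subtract_background(stack, ch, scale_um)` — a Gaussian high-pass: the
  channel minus its wide blur, clipped at zero. Scales of 10, 5 and 20 um
  are used for nuclei, Pros and Esg/RFP channels respectively. The scale is
  used as the sigma by default; an interpretation as a diameter
  (`scale_is_diameter = TRUE`) is provided because commercial tools do not
  document their convention.
* Borders are handled by symmetric (half-sample) reflection everywhere,
  which conserves total image intensity exactly for a normalized kernel.
  Large kernels run through an exact FFT path that is identical to direct
  convolution up to floating-point rounding.

## Detection

Nuclei and nuclear markers are detected with an anisotropic
scale-normalized Laplacian-of-Gaussian filter. For a requested object
diameter `D` per axis, the filter sigma is `D / (2 * sqrt(3))` — the scale
at which the 3D LoG response of a blob of diameter `D` peaks. Midgut nuclei
use 3.75 um xy (midpoint of the 3.5-4 um convention) and 5 um z; autophagy
puncta use 0.7 um isotropic. Spots are strict 26-neighbourhood maxima of
the response above a quality threshold, refined to sub-voxel precision by a
centre of mass within one radius; near-duplicates closer than one
anisotropy-normalized radius are suppressed, keeping the higher response.

The spot *quality* is defined as the LoG response itself (commercial
definitions are proprietary). The default threshold is Otsu's method on the
response distribution of all local maxima, which separates object maxima
from noise maxima without per-image hand tuning; the threshold actually
used is always recorded on the result. On noise-free fixtures the Otsu
default is meaningless (there are no noise maxima), so tests pass explicit
thresholds there.

Cytoplasmic reporters are segmented as surfaces: light smoothing, Otsu
threshold, 26-connectivity components, hole filling (a cytoplasmic shell
encloses its nucleus; the enclosed volume belongs to the cell), and a
minimum-volume gate. Because neighbouring cells' cytoplasm can blur into
one component at realistic spacing, `split_surfaces()` partitions the
segmented foreground by nearest detected nucleus (a Voronoi split seeded by
the nuclear channel) whenever per-cell objects are required — the puncta
pipeline does this automatically.

## Classification rules

With spots and surfaces in one physical frame, the typing logic is:

* distance from a spot to a surface = Euclidean distance from the spot
  centroid to the nearest foreground voxel centre, 0 if the centroid lies
  inside the surface. Measuring from the centroid (not the spot's bounding
  sphere) is a deliberate, consistently applied choice.
* "close" means distance <= threshold (ties count as close); 0.5 um is the
  default, 1 um the documented alternative, and the choice is recorded in
  provenance. Nearest-label assignment breaks exact ties toward the
  smaller label.
* EEP = Pros spots close to an Esg surface; mature EE = Pros spots far;
  total Esg+ cells = DAPI spots close to a surface; ISC = total Esg+ cells
  minus EEPs. The subtraction can go negative under detection noise; it is
  floored at zero with a structured warning.
* ReDDM: RFP spots far from Esg surfaces are newly differentiated cells —
  new EEs if colocalized with a Pros spot (5 um greedy nearest-pair
  matching, each spot used once), new enterocytes if colocalized with a
  nucleus but not Pros; Esg-close RFP spots colocalized with Pros are EEPs.
* puncta per cell: each punctum is assigned to the surface containing its
  centroid (nearest surface within the close threshold as a rescue);
  puncta outside every surface are reported in a remainder bin.
* percentages are always over the total DAPI count of the imaged field.

Two invariants hold by construction and are asserted across the test
suite: close/far is an exact partition of the input, and
EEP + mature EE always equals the Pros spot count.

## Reporter intensity (RFI)

The STAT-reporter workflow is two-track by design: object *definition* uses
the processed maximal projection (robust percentile rescale to [0, 1],
3x3 median filter, Otsu + distance-transform watershed, size gate), while
object *measurement* sums raw pixel values of the unmodified projection —
integrated, not mean, intensity, with one value per cell (objects are not
area-weighted; this is an explicit assumption). Per gut, the mean per-cell
intensity is computed and divided by the control-group mean — per batch
when batch labels exist — so the control mean is exactly 1 and the measure
is scale-invariant.

## Statistical layer

Shapiro-Wilk at alpha = 0.05 per group gates the family: parametric only
if every group passes (groups under n = 3 cannot be tested and force the
nonparametric path with a warning). Two groups: one-tailed unpaired Welch
t-test or Mann-Whitney; the tail is a required input because it encodes
the hypothesis and cannot be inferred from data. Three or more groups:
one-way ANOVA with Dunnett's test versus control (single-step
multivariate-t, via `multcomp`) or Kruskal-Wallis with midrank tie
correction followed by Dunn's z-tests versus control with Bonferroni
adjustment over the control-vs-treatment family only (matching
versus-control figure panels). Dunn's test is implemented in-package (no
installed package provides it) and is validated against the hand-evaluated
rank formula in the tests.

Survival uses `survival::survfit` / `survdiff`: the product-limit estimator
with censored flies leaving the risk set after their time, and the
Mantel-Cox log-rank chi-square with 1 df. qPCR fold changes use 2^-ddCt
with a Welch-type error-propagated confidence interval on replicate
delta-Ct values.

Significance stars follow the usual convention (`*` < 0.05 down to
`****` < 0.0001, `ns` otherwise).

```{r stats-example}
coh <- generate_survival_cohort(c(control = 0.04, rnai = 0.09),
                                n_per_group = 60, censor_prob = 0.05,
                                max_day = 60, seed = 2)
glance(logrank(coh, "control", "rnai"))
```

## What the synthetic generator emulates — and what it does not

`generate_midgut_stack()` draws per-class cell counts from a multinomial at
the planted proportions (the draw is recorded and is the ground truth),
places nuclei by rejection sampling with a minimum centre distance of one
anisotropy-normalized nucleus diameter (bounded at 10,000 attempts, then a
packing error), renders nuclei as anisotropic Gaussian blobs
(sigma = diameter / (2 sqrt 3), peak equal to the configured intensity at
the centre voxel), Esg as a Gaussian-profile cytoplasmic shell, and
nuclear markers per the class marker model. A Gaussian PSF is applied
last, followed by Poisson shot noise and additive Gaussian read noise —
the standard fluorescence noise model. Identical parameters and seed give
bit-identical stacks; each artifact uses its own seeded stream.

Two generator choices matter for interpretation:

* Esg-expressing classes are assigned to mutually well-separated nuclei
  (a farthest-candidate heuristic over the placed positions), emulating
  the sparse, scattered arrangement of progenitor nests and keeping
  cytoplasmic shells resolvable. Class counts still equal the recorded
  multinomial draw; only the spatial assignment is biased toward
  separation.
* Puncta are placed strictly within 85% of the parent nucleus ellipsoid
  with a minimum spacing of 1.2 puncta diameters, so planted counts are
  unambiguous.

The generator does not model gut curvature or regionalization, illumination
fields, spectral bleed-through, optical sectioning beyond a Gaussian PSF,
or clumped/overlapping nuclei. Passing recovery tests on these scenes
demonstrates that the measurement logic is correct and well-calibrated on
resolvable objects; it does not certify performance on crowded or
low-quality real acquisitions, where detection errors will propagate into
the subtraction rule for ISCs (hence the floored-at-zero warning).

Default scene conditions: 300 nuclei in a 102 x 102 x 16 um field at
(1, 0.4, 0.4) um voxels with planted proportions ISC 8%, EEP 4%, mature
EE 12%; intensity ~200 with Gaussian read noise sd 5 plus shot noise.
Puncta scenes use a finer (0.25, 0.2, 0.2) um pitch, 4 um cells, Poisson
mean 3 puncta/cell, and "SNR 5" meaning peak 250 against read noise
sd 50. Reporter scenes plant a 1.5x group factor with 15% lognormal
per-cell variation, 10 guts per group. These sizes are also the problem
sizes exercised by the acceptance checks (20 guts for population recovery,
100 random scenes for the proximity oracle, 200 cells for puncta recovery,
1000 replicates per statistical path for type-I calibration).

```{r generator-example}
g <- generate_midgut_stack(synthesis_params(n_cells = 60, seed = 1,
  image_shape_voxels = c(12, 160, 160)))
g$stack
count(g$truth, class)
```

## Numerical and degenerate-input choices

* Otsu thresholds are computed on a 256-bin histogram; constant inputs
  yield an empty mask (surfaces) or a degenerate-rescale warning with a
  zero image (projections).
* `rescale_and_denoise` clips at the 0.5 / 99.5 percentiles — a robust
  default; the assay definition does not pin these down.
* Local maxima are strict (`>` against all 26 neighbours); plateau ties
  are broken by sub-voxel refinement and duplicate suppression.
* Distance ties in proximity assignment go to the smallest label; the
  greedy colocalizer sorts candidate pairs by (distance, id, id) so
  results are deterministic.
* An empty foreground, an empty spot set, an all-censored cohort and an
  empty Pros channel are all valid inputs with defined outputs, not
  errors; a zero CFP denominator in the enteroblast ratio is an explicit
  error.
* Exhaustive nearest-voxel search is exact (vectorized in memory-bounded
  chunks); no spatial approximation is used anywhere in the proximity
  logic.

## Known limitations

* The 0.5-vs-1 um proximity threshold is exposed as configuration; the
  original workflow does not document which experiments used which, so no
  default can be claimed to match a specific figure.
* Spot quality is the LoG response, which need not match any commercial
  "quality" scale; thresholds are therefore not transferable from
  commercial software, only the Otsu default or explicit values.
* The per-cell table produced by `classify_populations()` attaches Pros
  status to nuclei by 5 um colocalization; the authoritative population
  counts use the subtraction rule, and the two can differ slightly under
  noise.
* Batch-wise RFI normalization requires a control in every batch;
  single-batch designs are normalized pooled.
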