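# midgutcyto

Image cytometry of *Drosophila* midgut cell populations from 3D confocal
stacks, for researchers quantifying intestinal stem-cell lineages.

The adult fly posterior midgut is maintained by intestinal stem cells
(ISCs) whose progeny are read out with a small marker algebra: DAPI marks
every nucleus; an Escargot (Esg) reporter fills the cytoplasm of ISCs and
progenitors; nuclear Prospero (Pros) marks enteroendocrine (EE) cells and
their progenitors; ReDDM lineage tracing adds a stable nuclear RFP
inherited by differentiated progeny; Ref(2)P/p62 puncta report blocked
autophagy; and 10XSTAT-GFP intensity reports JAK-STAT activity.
`midgutcyto` implements the full quantification chain:

* **Preprocess** — anisotropic Gaussian smoothing (0.6 µm), Gaussian
  high-pass background subtraction (10/5/20 µm per channel), maximal
  projection, robust rescale + median denoise; all parameters in µm.
* **Detect** — anisotropic scale-normalized Laplacian-of-Gaussian spot
  detection (σ = D/(2√3); nuclei 3.75 µm xy / 5 µm z, puncta 0.7 µm),
  Otsu-thresholded surface segmentation with hole filling and
  nucleus-seeded splitting, CellProfiler-style 2D primary objects.
* **Classify** — the proximity rules of midgut cytometry:
  EEP = Pros⁺ spots within 0.5 µm of an Esg surface; mature
  EE = Pros⁺ spots far from every surface; ISC = (DAPI⁺ spots close to a
  surface) − EEP; ReDDM progeny typed by RFP/Esg/Pros combinatorics with
  5 µm spot colocalization; puncta-per-cell counting; mitotic (pH3) and
  enteroblast ratios. Percentages are always over total DAPI⁺ nuclei.
* **Intensity** — integrated reporter intensity per cell on the raw
  projection (segmentation on the processed one), per-gut means,
  normalized relative fluorescence (RFI, control mean ≡ 1).
* **Stats** — Shapiro-Wilk-gated test selection; one-tailed t /
  Mann-Whitney; ANOVA + Dunnett or Kruskal-Wallis + Dunn vs control;
  Kaplan-Meier + Mantel-Cox log-rank; 2^−ΔΔCt fold changes with
  propagated CIs; figure-style significance stars.
* **Synthesize** — seeded generators for multichannel gut stacks, puncta
  scenes, survival cohorts and Ct tables with exact ground-truth
  sidecars, so the entire pipeline is testable without microscope data.

Everything is tidyverse-shaped: spot sets, cell tables, population
counts, survival and Ct tables are tibbles; fitted results have
`tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

Simulate one gut with planted proportions, run the population pipeline,
and compare with the ground truth:

```r
library(midgutcyto)

g <- generate_midgut_stack(synthesis_params(n_cells = 120, seed = 42,
  image_shape_voxels = c(14, 200, 200)))
res <- run_pipeline(run_config(mode = "populations"), g$stack)
res$counts
#> # A tibble: 3 × 4
#>   class     count total_nuclei percent
#>   <chr>     <int>        <int>   <dbl>
#> 1 ISC          14          120   11.7
#> 2 EEP           8          120    6.67
#> 3 EE_mature    11          120    9.17

100 * table(g$truth$class) / nrow(g$truth)
#> EE_mature       EEP       ISC     other
#>  9.166667  6.666667 11.666667 72.500000
```

The recovered percentages (11.7% ISC, 6.67% EEP, 9.17% mature EE over 120
nuclei) match the planted truth exactly on this noise-level scene: every
nucleus was detected, and the proximity rules re-derived each planted
class. A survival comparison on a simulated lifespan cohort:

```r
coh <- generate_survival_cohort(c(control = 0.04, rnai = 0.09),
  n_per_group = 60, censor_prob = 0.05, max_day = 60, seed = 2)
glance(logrank(coh, "control", "rnai"))
#> # A tibble: 1 × 4
#>   method              statistic    p_value stars
#>   <chr>                   <dbl>      <dbl> <chr>
#> 1 Mantel-Cox log-rank      20.7 0.00000546 ****
```

The chi-square of 20.7 (1 df) says the RNAi group's hazard (0.09/day
planted vs 0.04/day control) separates the survival curves far beyond
chance; `autoplot(km_estimate(coh))` draws the Kaplan-Meier curves.

A thin CLI over the same functions is at `inst/cli/midgutcyto.R`
(subcommands `simulate`, `quantify`, `lineage`, `puncta`, `intensity`,
`survive`).

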