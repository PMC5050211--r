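---
title: "Cube-based quantification of submerged biofilm stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cube-based quantification of submerged biofilm stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmcubes)
```

## The measurement problem

Static submerged *E. coli* biofilms are spatially heterogeneous: dense
aggregates and microcolonies sit in the lower tens of micrometres of the
well, motile single cells disperse through the liquid column, and a pellicle
can form at the liquid–air interface. Gene expression differs between these
subpopulations — curli (matrix) genes switch ON in aggregated cells,
flagellar genes mark motile singles, the general stress sigma factor
σ^S^ is only partially correlated with curli, and TIMER-based growth-rate
reporters show slow growth concentrated in the densest regions. To quantify
this from confocal z-stacks, `biofilmcubes` implements a volumetric pipeline
whose unit of measurement is a small cube of segmented biomass, plus the
matching flow-cytometry event analysis.

## The pipeline

1. **Isotropic upsampling** (`upsample_to_isotropic`). Confocal stacks
   sample z more coarsely than x/y. The stack is linearly interpolated
   along z to the lateral spacing. The output grid is aligned to the first
   slice centre with step equal to the target spacing, so acquired slices
   are retained and intermediate slices interpolated; linear interpolation
   is convex, so no overshoot is possible. The physical extent can fall
   short by up to one axial input spacing at the top of the stack (one
   output voxel at the default 2× factor).
2. **Denoising** (`smooth_stack`). A uniform averaging filter of radius 1
   voxel (3×3×3) by default. Mirror (reflect) padding avoids artificial
   darkening at the substratum plane, where biomass touches the image
   border. The kernel size is configurable; radius 1 is the smallest
   non-trivial choice, appropriate because segmentation (not the smoothed
   values) is the only consumer.
3. **Segmentation** (`otsu3_thresholds`, `segment`). Three-class Otsu
   thresholding on a 256-bin equal-width histogram of the full volume;
   class 1 (background) is discarded and classes 2–3 (dim and bright
   biomass) form the binary mask. The exhaustive threshold search is
   deterministic, with ties broken toward the lexicographically smallest
   pair. Histograms with fewer than three populated bins raise an error
   rather than silently producing an empty or full mask — this surfaces
   misconfigured synthetic scenes immediately. Thresholds are computed
   per stack, matching independent processing of replicate images.
4. **Merging** (`merge_masks`). When no constitutive marker is available
   (dual-reporter mode), each reporter channel is segmented individually
   and the masks are merged by voxelwise union before dissection.
5. **Cube dissection** (`dissect`). The mask is partitioned into a
   non-overlapping grid of cubes of 5 voxels per side. Partial cubes at
   the far borders are retained with their true voxel counts; dropping
   them would bias depth profiles at the biofilm top. Per cube we record
   the foreground-voxel count, the unweighted centre of mass of
   foreground voxel centres, and the mean *raw* (unsmoothed, unprocessed)
   intensity of every channel over the foreground voxels only. Averaging
   over all voxels of the cube instead would couple intensity to
   occupancy; the foreground-only choice is an explicit assumption.
6. **Local density** (`local_density`, `annotate_density`). The occupied
   volume fraction inside a solid ball of 3 µm radius around each cube's
   centre of mass — the proxy for aggregate/microcolony membership. The
   ball is solid, not a hollow shell: a hollow reading would ignore the
   cube's own neighbourhood core. At image boundaries the denominator is
   the in-bounds ball voxel count, so densities at the substratum (where
   the densest biomass sits) are not systematically underestimated.
7. **Surface topography** (`height_map`, `roughness_map`). Height is the
   physical z of the topmost foreground voxel centre per (y, x) column,
   with the substratum at z = 0 and voxel-centre coordinates
   ((index + 0.5) × spacing). Roughness is the windowed standard
   deviation (11 px window) of the defined heights; no standard estimator
   exists for this quantity, so the windowed SD is isolated behind one
   operation and alternatives can be swapped without touching anything
   else. It is invariant to constant height shifts and exactly zero for a
   flat slab.
8. **Profiles and ratios** (`density_z_profile`, `expression_vs_density`,
   `expression_z_profile`, `normalize_channel`, `timer_ratio`,
   `classify_cubes`). Reporter intensities are normalised per cube by the
   constitutive reference (or, for TIMER, orange by the internal green
   control); cubes whose reference is at or below the floor (default 0)
   are excluded and counted. 2-D histograms of expression against local
   density or depth conserve the included-cube count exactly. In
   dual-reporter mode a cube is called positive for a channel when at
   least one of its voxels is foreground in that channel's individual
   mask — the sharp cutoffs this induces in expression scatter plots are
   the segmentation thresholds themselves.

## Flow-cytometry module

Events are signed values after subtraction of the control's **median**
channel value (robust to control outliers; commercial cytometry suites
apply a software-defined baseline whose statistic is not documented).
Negative values are retained — they
are the expected signature of background subtraction, not an error. For
display and gating the values are passed through a biexponential transform
`T(x) = asinh(x / cofactor) / ln 10` with cofactor 150: linear near zero
(negative values keep their sign), base-10 logarithmic at large magnitude,
odd and exactly invertible. The exact transform used by commercial
cytometry software is proprietary; this scaled inverse hyperbolic sine is
the standard published stand-in with the same qualitative behaviour, and
the cofactor is configurable. ON/OFF gating thresholds the transformed
values, by default at the two-class Otsu optimum of their 256-bin
histogram; events exactly at the threshold count OFF (conservative ON
calls), and the ON and OFF percentages are exact complements. Group
summaries are always computed on untransformed values, because averaging
transformed values biases the means of skewed distributions. Crystal-violet
biomass values are normalised by the culture OD₆₀₀ (`normalize_cv`).

## The synthetic-scene generator

No imaging data accompany the study this pipeline targets, so validation
rests on a ground-truthed generator (`generate_scene`, `render_scene`,
`generate_events`) whose defaults encode the default study condition:

* **Three subpopulations.** Curli-ON cells concentrated in aggregates
  (P(curli ON | aggregate) = 0.9), flagella-ON motile singles
  (flagella mark non-curli *single* cells; aggregated or pellicle
  curli-OFF cells are the stationary OFF/OFF subpopulation), and strictly
  exclusive curli/flagella expression by default (`epsilon_double = 0`);
  a positive `epsilon_double` forces the stated fraction of
  double-positive cells.
* **Geometry.** 300 single cells and 12 aggregates of 80 cells packed
  uniformly in balls of 3.5 µm radius, with aggregate centres below
  40 µm, in a 64 × 64 × 64 µm domain. Cells are prolate spheroids with
  semi-axes 0.5 × 0.5 × 1.0 µm (a rod-shaped bacterium lying flat).
  Singles are placed uniformly in the free volume — draws falling within
  one cell length of an aggregate ball are resampled, since a dispersed
  cell cannot physically occupy a packed aggregate. No quantitative
  aggregate size or count distribution is available to match, so these
  are labelled placeholders, chosen so that structures dominate the
  biomass (as the target images show) and every rendered reporter channel
  carries enough signal mass for histogram-based segmentation; they are
  all configurable. The composition matters for tertile-based summaries:
  with singles dominating the cube population, the top local-density
  tertile dips below the aggregate population and mixes the classes.
* **σ^S coupling.** σ^S activity is bimodal (levels 0/1);
  P(high | curli OFF) is `p_sigmaS_high_given_curli_off` and
  P(high | curli ON) interpolates from it toward 1 with `rho_sigmaS`, so
  both σ^S-high/curli-OFF and σ^S-low/curli-ON cells exist — the partial
  correlation the pipeline must recover.
* **Growth rate.** TIMER green is 1 for every cell; orange equals the
  class ratio (2.0 in aggregates, 0.5 in singles), so per-class recovered
  ratios have exact truths.
* **Optics.** Voxel spacing (1.0, 0.5, 0.5) µm — anisotropic in z so
  upsampling is exercised by default — Gaussian PSF with σ =
  (0.6, 0.25, 0.25) µm, amplitude 150 for ON states, background 2 counts,
  Poisson shot noise and Gaussian read noise of 1 count: a
  photon-counting-style confocal model in which the background offset and
  its spread are small. The rendered intensity of a 1 µm-thick cell under
  the axial PSF is a dim continuum rather than a solid plateau, so a
  reporter channel needs a few hundred expressing cells before its
  histogram separates cleanly from background — the reason the default
  scene keeps each reporter above that mass.
* **Events.** A two-component mixture: OFF is Gaussian around 0 with SD
  30 on the signed post-subtraction scale, ON is log-normal with median
  1000; `f_on = 0.30`, 50 000 events.

What the generator does **not** emulate: mechanistic growth, chemical
gradients, cell division, optical aberrations beyond a Gaussian PSF,
spectral bleed-through, or depth-dependent attenuation. Passing the
end-to-end tests therefore demonstrates that the pipeline recovers known
structure from images with realistic sampling and shot noise — not that it
is robust to every artefact of real microscopy.

## Numerical and design choices

* 5-voxel cubes on the default 0.5 µm isotropic grid are 2.5 µm on a
  side; the cube side is specified in voxels, so finer acquisitions give
  proportionally finer cubes.
* All voxel coordinates use the voxel-centre convention,
  ((index + 0.5) × spacing) per axis with 0-based indices, making centres
  of mass and ball membership unambiguous.
* `local_density` is evaluated by exact enumeration of voxel centres in
  the ball (tests compare it against an independent brute-force loop);
  nothing is approximated by convolution, so values at arbitrary
  (off-grid) points are exact.
* One pipeline seed is split deterministically into per-stage substreams
  (scene, optics, events), giving byte-identical tabular outputs across
  runs and stage-level independence.
* Degenerate inputs fail loudly: constant or two-valued volumes refuse to
  segment, empty control tables refuse to subtract, impossible aggregate
  packings refuse to generate.
* TIFF is the only image dialect; spacing, channel names and the storage
  dtype travel in a JSON sidecar written next to each file, because the
  R TIFF writer exposes no tag interface. Integer intensities round-trip
  bit-exactly; float stacks are stored as scaled 32-bit float.
  Proprietary microscope formats must be converted upstream.

Problem sizes in the test-suite and acceptance script (20 end-to-end seeds
for exclusivity, 10 for the reported summary, 3 σ^S scenes, 2 TIMER scenes,
200 histograms and 50 density triples for the oracles) were chosen as the
smallest runs whose binomial/oracle tolerances are meaningful at the stated
thresholds.

## Known limitations

* Otsu-based segmentation assumes the channel histogram contains an
  appreciable foreground mode. Channels in which only a handful of cells
  express (well under a few hundred at the default optics) can have their
  lower threshold placed inside the background distribution; the
  foreground fraction is logged on every run so such cases are visible.
* The roughness estimator (windowed SD of topmost-voxel height) is one of
  several defensible definitions; absolute roughness values should not be
  compared across tools, only within a pipeline.
* Cube-level positivity fractions approximate cell-level fractions only
  when cubes and cells correspond roughly one-to-one (dispersed cells);
  inside aggregates, one cube spans several cells.
* The biexponential here is a display/gating scale, not a fitted logicle
  transform; no compensation or doublet discrimination is performed.
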