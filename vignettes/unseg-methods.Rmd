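---
title: "Unsupervised two-channel segmentation of cells and nuclei: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised two-channel segmentation of cells and nuclei: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unseg)
```

## The problem and the model

Multiplexed immunofluorescence imaging of tissue produces images in which a
nucleus marker (Hoechst, DRAQ5) and a cell-membrane marker (Na+K+ATPase,
CD20, ...) jointly carry enough contrast for a human to delineate every cell
-- but cells in tissue are crowded, their shapes deviate from convexity, and
marker expression is spatially heterogeneous. This package segments nucleus
and cell instances from such a two-channel image without any training data,
by treating pixel classification as a Bayesian-like fusion of two
ingredients computed from the image itself:

1. **A-priori probability.** For each channel $i$, an initial foreground
   estimate (Gaussian smoothing followed by three-class Otsu, keeping
   pixels above the lower threshold) selects a sample of marker-positive
   intensities. The empirical CDF $\mathcal{F}_i$ of that sample, evaluated
   at every pixel, gives the prior $P_i^e(x,y) = \mathcal{F}_i(I_i(x,y))$:
   the brighter the marker, the higher the prior. Two mask families refine
   this field. The *global mask* $M_i^g$ keeps pixels that survive a local
   mean suppression filter (LMSF) at every window half-width in `n0_list`
   -- a pixel is zeroed when its intensity falls below `t0` times its local
   window mean, which carves out the dark valleys between adjacent cells at
   several spatial scales -- and whose prior exceeds a small floor `p1`/`p2`
   (default 0.01). The *local mask* $M_i^l$ applies a per-pixel two-class
   Otsu threshold over a disk of radius `r0` to a gradient-adaptive-smoothed
   (GAS) copy of the channel, then is restricted to $M_i^g$; it captures
   local morphology that a single global threshold misses.

2. **Contrast likelihood.** The signed contrast
   $L_0 = (I_2 - I_1)/(I_2 + I_1)$, evaluated only where either channel
   exceeds its minimum intensity over the corresponding local-mask support,
   and sign-gated by the global masks, yields a likelihood $L \in [-1, 1]$:
   $-1$ is unambiguous nucleus evidence, $+1$ unambiguous membrane
   evidence, $0$ no evidence.

The posterior fields combine the two: with the prior saturated to 1 on the
local mask ($P_i^s$), the global posteriors are
$P_1^g = P_1^s + (1 - P_1^s)\,|L|$ where $L < 0$ (else 0) and symmetrically
$P_2^g$ where $L > 0$. By construction $P_1^g \cdot P_2^g = 0$ at every
pixel and both fields stay in $[0,1]$. An argmax over $(P_1^g, P_2^g)$
(k-means over the probability pairs is available as an alternative) yields
the global semantic map $M^g \in \{$background, nucleus, membrane$\}$; the
priors restricted to the local masks yield the local semantic map $M^l$ the
same way.

The instance stages then parse these semantic maps:

3. **Nucleus instances.** Every connected component of the nucleus class is
   classified by *convexity analysis*: components of area $\le$ `a0` are
   discarded, and a component whose steepest concave point (SCP; the
   boundary pixel deepest below the convex hull) exceeds `d0` is a nucleus
   cluster to be split. Clusters are split by the *perturbed watershed*:
   membrane evidence from $M^l$ first cuts the cluster; seeds are the
   distance-transform (DT) maxima of the regions where DT $\ge$ d_avr (the
   mean non-zero DT value); a marker-controlled watershed on $-$DT gives the
   initial split; then all seeds are shifted simultaneously by
   $\pm\lfloor d_{avr}\rfloor$ in each axis direction, and any seed whose
   region collapses to at most `collapse_area` pixels under any shift (or
   whose shifted position leaves the mask) is spurious and removed. The
   final watershed uses the surviving seeds on the unperturbed DT, and each
   sub-region re-enters convexity analysis (recursion capped by
   `max_recursion` and by strict area decrease). When a non-convex cluster
   resists splitting -- typically without membrane evidence, where DT
   thresholding finds a single plateau -- *virtual cuts* draw a line
   through the SCP perpendicular to the hull chord spanning the concavity;
   the two virtual halves only donate their DT maxima as seeds, and the
   watershed runs on the uncut mask. Small candidates (below
   `sc_area_factor` times the median candidate area) are kept only when
   isolated. Each final instance gets morphological closing-then-opening
   boundary smoothing with a disk of `smoothing_radius`.

4. **Cell instances.** Each cell starts as its nucleus and grows by
   multi-source shortest-path competition: entering a pixel costs its step
   length times $1 + \beta P_2^g$ (`membrane_cost_beta`), with a total
   budget of `u0`. Growth is therefore cheap through membrane-free
   cytoplasm, expensive across membrane evidence, and neighbouring cells
   meet along walls. Nuclei with membrane evidence around them (at least
   `membrane_support_frac` of 10-degree angular sectors within `u0`+2 px)
   also annex the adjacent membrane wall, so the cell boundary coincides
   with the far side of its membrane; nuclei without support keep their
   `u0`-dilation clipped against neighbours -- for an isolated nucleus this
   is exactly the morphological dilation. Finally, closed membrane contours
   that contain no nucleus are recovered from the skeleton of the membrane
   class: a skeleton loop has Euler number 0 (one enclosed hole), and each
   hole larger than half the mean nucleus area, overlapping existing cells
   by less than `nucleus_free_overlap`, becomes a nucleus-free cell.

Because cells are grown from nuclei, every nucleus lies inside exactly one
cell on every run -- the pipeline asserts this containment guarantee, the
posterior exclusivity, and instance disjointness each time `run_unseg()`
executes.

## Parameters

| Parameter | Default | Unit | Role |
|---|---|---|---|
| `sigma` | 3 | px | Gaussian blur before the three-class Otsu foreground estimate |
| `t0` | 0.5 | ratio | LMSF suppression threshold |
| `n0_list` | 5, 10, 20, 40 | px | LMSF window half-widths (valley scales) |
| `p1`, `p2` | 0.01 | prob. | prior floor in the global masks |
| `k0` | 1 | -- | GAS smoothing scale |
| `r0` | 5 | px | local Otsu disk radius |
| `a0` | 20 | px | minimal component area (primary) |
| `d0` | 4 | px | SCP depth separating nuclei from clusters (primary) |
| `u0` | 9 | px | expansion budget / fallback dilation (valid 1-10) |
| `collapse_area` | 4 | px | point-object size in the perturbation test |
| `smoothing_radius` | 1 | px | boundary smoothing disk |
| `membrane_cost_beta` | 20 | -- | wall-crossing cost multiplier |
| `membrane_support_frac` | 0.25 | frac. | angular membrane coverage for expansion |

`a0` and `d0` are the two parameters users should adjust first: `a0` is the
debris cutoff in pixels and scales with magnification; `d0` decides how
deep a concavity must be before a component is treated as a cluster of
nuclei rather than one irregular nucleus, so smaller `d0` splits more
aggressively.

## What the synthetic generator emulates

`generate_tissue()` renders ellipse nuclei with radial intensity falloff
and per-cell peak jitter, membrane rings of configurable width and angular
completeness (one random arc deleted), touching pairs/triples that share
flat membrane walls, cells without membrane, closed rings without a
nucleus, and additive Gaussian noise clipped to $[0,1]$ -- with exact
instance ground truth by construction and full determinism per seed.
`generate_cluster()` renders controlled fused-disk geometries for the
cluster-splitting machinery.

The default background noise is `noise_sd = 0.002` of the normalized
dynamic range. This emulates the regime of real min-max normalized 16-bit
fluorescence acquisitions, whose background fluctuations (camera read
noise) sit orders of magnitude below the stain signal. The choice is load
bearing and worth stating plainly: the prior CDF is built over a
*smoothed-image* foreground support, so a fixed fraction of its sample are
blur-halo pixels whose raw values are background noise; the background's
prior is then roughly that pollution fraction regardless of the noise
scale, and the 0.01 prior floor alone cannot reject it. What actually
suppresses background is the likelihood qualification ($I_i$ must exceed
the local-mask minimum $i_i$), and that works when background fluctuations
stay below the 256-bin histogram quantization of the local Otsu -- as in
real normalized data. Consequently, passing tests demonstrate robustness to
realistic read noise, partial membranes, touching clusters and intensity
heterogeneity; they do not demonstrate robustness to background noise at
several percent of the dynamic range, to out-of-focus haze, or to textured
autofluorescent background, none of which the generator draws.

## Numerical choices and degenerate inputs

- All Otsu thresholds use 256-bin histograms of $[0,1]$ intensities;
  thresholds are bin indices and "above threshold" means a strictly larger
  bin. Zero-variance local neighbourhoods are background.
- LMSF window sums use zero padding with the full-window divisor, exactly
  as the filter's defining sum states, so border pixels see a deflated
  mean; this is logged as an edge caveat rather than hidden by
  renormalization.
- The GAS gradient uses central differences with replicated borders (the
  defining expression's second gradient term is read as a typo for the same
  image), and its 3x3 weighted mean also replicates borders, so constant
  images are fixed points.
- Distance transforms are Euclidean; floors ($\lfloor d_{avr}\rfloor$)
  follow the floor notation in the perturbation definition. Seed ties at
  equal DT break to the lexicographically smallest (row, col); flooding
  ties break first-in-first-out, so every stage is deterministic in argmax
  mode.
- Components and watershed regions use 8-connectivity; hole counting uses
  the dual 4-connectivity.
- Convexity is measured against the hull polygon of boundary pixel
  centres. A discrete disk deviates up to about 0.8 px from that polygon,
  so "convex" means depth at most 1 px; `d0` (4 px) is far above this
  floor.
- A constant channel normalizes to all zeros and flows through the whole
  pipeline (empty masks, zero likelihood) rather than erroring; an image
  with an empty foreground estimate does the same with a message. The
  empty-versus-empty F1 is defined as 1 with a warning.
- K-means labelling initializes at (0,0), (1,0), (0,1) in probability
  space, drops anchors that attract no points, and maps each final cluster
  to the class its centre favours; the hard background constraint
  ($P_1 = P_2 = 0$) is applied before clustering.

## Design choices where the procedure was open

- **Cell expansion.** "Grow until the boundary coincides with the closest
  membrane" is realized as accumulated-cost (Dijkstra) competition rather
  than a static-priority watershed: with a static priority, a cell that
  finds a gap in its membrane ring floods the whole neighbourhood beyond
  it, because ordering by local potential ignores how far growth has
  travelled. Accumulated cost penalizes every membrane crossing and every
  extra pixel of path, which both stops growth at walls and bounds
  gap leakage.
- **Membrane support.** Whether a nucleus has a membrane to grow to is
  decided by angular coverage (fraction of 10-degree sectors containing
  membrane within `u0`+2 px), not by the areal fraction of its
  neighbourhood that is membrane: a complete but thin ring covers all
  sectors while occupying only ~15% of the annulus area.
- **Nucleus-free cells.** Closed contours are found as holes enclosed by
  skeleton loops (Euler number 0 for a single loop). Working with skeleton
  loops instead of the mask-minus-skeleton residual keeps the detection
  valid for membrane bands only 2-3 px wide, whose residual fragments into
  single-pixel debris.
- **Small components.** The small-component cutoff is
  `sc_area_factor` (0.5) times the median accepted-candidate area, and
  "isolated" means a 2-px dilation touches no other accepted nucleus; both
  are configurable because the underlying criterion is a judgement call.
- **Virtual cut direction.** Through the SCP, perpendicular to the hull
  chord spanning the concavity -- the direction that crosses the neck of a
  waist-shaped cluster.

## Problem sizes in the test and acceptance suites

The shipped tests run entirely on generated fixtures: unit fixtures of
64-300 px, a 512 x 512 benchmark with 60 nuclei (20% in touching pairs),
100 fused-disk pairs for the splitting-rate check, and a runtime probe over
50-400 cells at constant density (images up to ~1360 px). These sizes keep
the whole suite within a few minutes on one core while exercising every
stage; the pipeline itself has no image-size limit and its runtime scales
with segmented-cell count, as the probe verifies.

## Known limitations

- The method presumes both channels are informative; a nucleus channel with
  no usable foreground yields no nuclei (and then no cells beyond
  membrane-only contours).
- Background suppression relies on background fluctuations being small on
  the normalized scale (see the generator section); heavily haze-affected
  or low-bit-depth data would need pre-processing.
- Cell growth is capped at `u0` pixels from the nucleus, so cytoplasm
  extending further than `u0` beyond its nucleus is truncated; raise `u0`
  (valid range 1-10) for large cells at high magnification.
- Multi-nucleated cells are segmented as separate cells; handling them
  requires a third, nuclear-envelope channel, which is out of scope.
- The perturbed watershed is exposed as a standalone, modality-agnostic
  utility (`perturbed_watershed()`, `virtual_cuts()`) and can be used on
  any binary mask, but its defaults are tuned for nucleus-scale objects
  (tens of pixels across).
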