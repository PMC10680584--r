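# unseg

Unsupervised instance segmentation of cells and their nuclei in two-channel
fluorescence images of tissue — one nucleus-marker channel (Hoechst, DRAQ5)
and one cell-membrane-marker channel (Na⁺K⁺ATPase, CD20, …). No training
data, no model weights: the segmentation is computed from each image's own
intensity statistics, which makes the method adaptable per image and fully
explainable. It is aimed at researchers quantifying multiplexed
immunofluorescence (CODEX/CyCIF-style) tissue data who need
nucleus/cytoplasm/membrane compartments that are *internally consistent* —
every segmented nucleus is guaranteed to lie inside exactly one segmented
cell.

## Method at a glance

For normalized channels $I_1, I_2 : \Omega \to [0,1]$:

1. **Prior.** Per channel, an empirical CDF $\mathcal{F}_i$ over an
   Otsu-selected foreground sample gives the a-priori probability
   $P_i^e = \mathcal{F}_i(I_i)$; a multi-scale local-mean suppression
   filter plus the floor $P_i^e \ge p_i$ builds the global mask $M_i^g$,
   and a disk-windowed local Otsu on a gradient-adaptive-smoothed copy
   builds the local mask $M_i^l \subseteq M_i^g$.
2. **Likelihood.** The signed contrast
   $L = (I_2 - I_1)/(I_2 + I_1) \in [-1, 1]$ (qualified by per-channel
   minima over the local masks and sign-gated by the global masks) scores
   nucleus ($L<0$) versus membrane ($L>0$) evidence.
3. **Posterior.** $P_1^g = P_1^s + (1-P_1^s)|L|$ on $\{L<0\}$ and
   symmetrically $P_2^g$ on $\{L>0\}$ (with $P_i^s$ the prior saturated on
   $M_i^l$); argmax with a hard background rule gives semantic maps
   $\Omega \to \{\text{bg}, \text{nucleus}, \text{membrane}\}$.
4. **Instances.** Nucleus-class components are split by convexity analysis
   (area $a_0$, concavity depth $d_0$), a **perturbed watershed** — seeds
   from distance-transform plateaus are shifted by
   $\pm\lfloor d_{avr}\rfloor$ in all four directions and regions that
   collapse under any shift are removed as spurious — and **virtual cuts**
   through the steepest concave point when thresholding under-seeds. Cells
   then grow from their nuclei by membrane-penalized geodesic competition
   (budget $u_0$, plain $u_0$-dilation where no membrane exists), and
   closed membrane contours without a nucleus are recovered via
   skeleton-loop (Euler number) analysis.

Evaluation follows object-matching at an IoU threshold with
$F_1 = 2\,TP / (2\,TP + FP + FN)$ and $F_1$-versus-IoU curves.

The perturbed watershed and virtual cuts are exported as standalone,
modality-agnostic utilities (`perturbed_watershed()`, `virtual_cuts()`) —
they apply to any binary mask wherever a classical marker watershed would.

## Worked example

Everything below runs on a synthetic tissue image with exact ground truth —
the package ships a generator, so the example is fully reproducible.

```r
library(unseg)

bundle <- generate_tissue(fixture_spec(size = c(256L, 256L),
                                       n_cells = 15L, seed = 1L))
res <- run_unseg(bundle$image, verbose = TRUE)
#> channel 1: global mask 5808 px, local mask 2811 px
#> channel 2: global mask 4487 px, local mask 2398 px
#> segmented 15 nuclei and 16 cells

f1_curve(res$nuclei, bundle$gt_nuclei, c(0.5, 0.7, 0.9))
#>   threshold TP FP FN        f1
#> 1       0.5 15  0  0 1.0000000
#> 2       0.7 15  0  0 1.0000000
#> 3       0.9 11  4  4 0.7333333

f1_curve(res$cells, bundle$gt_cells, c(0.5, 0.7, 0.9))
#>   threshold TP FP FN     f1
#> 1       0.5 15  1  1 0.9375
#> 2       0.7 14  2  2 0.8750
#> 3       0.9  8  8  8 0.5000

head(res$records, 4)
#>   cell_id nucleus_id           origin
#> 1       1          1         expanded
#> 2       2          2         expanded
#> 3       3          3         expanded
#> 4       4          5 dilated_fallback
```

The fixture contains 15 nucleated cells (one of them membrane-free, hence
the `dilated_fallback` origin) plus one nucleus-free membrane ring, which
the pipeline recovers as a 16th cell. All 15 nuclei are found with IoU
above 0.7 against ground truth; the cell F1 at the conventional IoU 0.5 is
0.94. `write_outputs(res$nuclei, res$cells, "out/")` writes 16-bit label
TIFFs and an object table CSV.

A command-line wrapper ships in `inst/scripts/unseg`
(`segment`, `evaluate`, `simulate` subcommands):

```sh
$(Rscript -e 'cat(system.file("scripts/unseg", package="unseg"))') \
  segment --image img.tif --nucleus-ch 0 --membrane-ch 1 --out out/
```

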