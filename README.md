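# pectoshed

Pectoral muscle identification in mediolateral-oblique (MLO) mammograms by
watershed transformation and seeded catchment-basin merging.

In an MLO view the pectoral muscle is a bright, roughly triangular region
at the top of the chest-wall side of the image. Because its brightness
biases density estimation and lesion detection, removing it is a standard
preprocessing step for computer-aided breast-cancer detection. Its edge is
frequently curved and locally low-contrast, which defeats straight-line
detectors; `pectoshed` instead detects it as a region boundary:

1. **ROI extraction** — normalise to left-MLO orientation, area-downsample
   to a 256×256 working grid, strip the unexposed film border, cut the
   rectangle from the chest wall to the skin–air boundary.
2. **Watershed transform** — flood the 3×3-mean-smoothed Sobel gradient
   magnitude `G = sqrt(Gx^2 + Gy^2)` with an immersion (Vincent–Soille)
   watershed over the 8-connected pixel graph: one catchment basin per
   regional minimum, thin dam (watershed) pixels between basins.
3. **Seeded merging** — starting from the basin holding the top-left ROI
   pixel, merge every neighbouring basin whose inter-region edge mean
   (IRM, mean `|ΔI|` over crossing edges of the original ROI) does not
   exceed the dynamic threshold

   ```
   DT = max( IRA(seed) + C·NR/|seed| ,  IRA(nbr) + C·NR/|nbr| ),   C = 1
   ```

   where IRA is a region's mean internal edge weight and NR the number of
   basins. The final seed is the muscle; its right-most column per row is
   the boundary.

Evaluation metrics (area-normalized FP/FN over per-row boundary columns,
and the Hausdorff distance between boundary point sets in px and mm) and a
synthetic left-MLO phantom generator with exact ground truth are included,
so the whole pipeline runs and is tested without any external data.

## Worked example

```r
library(pectoshed)

ph  <- generate_phantom(phantom_spec(noise_sd = 0))   # clean phantom
res <- run_pipeline(ph$image, pipeline_config(side = "left"))
res
#> <pipeline_result> left-MLO input, 3 basins -> seed 1 (6981 px working)

evaluate_boundary(res$boundary_working, ph$truth_boundary,
                  truth_area = ph$truth_area, pixel_mm = 0.8)
#> <evaluation_result> FP 0.0134  FN 0.0000  Hausdorff 1.00 px (0.80 mm)

res$merge$log
#>   iteration neighbour direct_edges irm         dt merged
#> 1         1         2           20  40 0.04365415  FALSE
```

The watershed finds three basins (muscle, tissue, air); merging tests the
tissue basin once and refuses it — its contrast (IRM = 40) dwarfs the
dynamic threshold (≈ 0.04) — so the seed is exactly the muscle basin. FP
0.0134 means 1.3 % of the true muscle area is overshoot (the absorbed
one-pixel dam line); FN 0 means no undershoot; the boundary is within one
pixel of the constructed truth everywhere.

On heavily oversegmented inputs (the default phantom's white noise sd 5
yields ~2000 basins) the `NR/|region|` terms dominate any 8-bit contrast
and the merge criterion stops being selective; see the methods vignette
(`vignettes/pectoral-watershed.Rmd`) for the analysis and for every
numerical choice and its rationale.

## Command line

```sh
Rscript inst/cli/pectoshed.R segment input.pgm --side auto --out results/
Rscript inst/cli/pectoshed.R evaluate results/pectoral_mask.pgm truth.pgm --pixel-mm 0.8
Rscript inst/cli/pectoshed.R phantom --n 5 --seed 7 --out phantoms/
```

Masks are written as PGM (255 = muscle), boundaries as CSV with 0-based
`row,col` coordinates, metrics and run logs as JSON.

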