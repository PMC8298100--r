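# invquant

Quantitative analysis of intracellular nanovesicle (INV) trafficking
assays, in R.

INVs are ~30-nm transport vesicles marked by the TPD52-like proteins
(TPD52/TPD53/TPD54). Experiments probing them generate several distinct
quantitative readouts, and `invquant` implements the full analysis layer
for all of them:

| Module | Readout | Core statistic |
|---|---|---|
| `stvariance` | live-cell movies of sub-resolution vesicles | spatiotemporal variance: mean per-pixel temporal variance after per-frame mean normalization |
| `mito` | mitochondrial aggregation after vesicle capture | per-object circularity fcirc = 4πA/P², median per cell over objects > 0.2 µm² |
| `screen` | knocksideways (rapamycin rerouting) Rab screens | F_post/F_pre intensity ratio; Dunnett many-to-one test vs control; BCa bootstrap effect sizes (10⁵ replications); Z-score matrix + hierarchical clustering |
| `migration` | 2D cell tracking | speed, cumulative distance, directionality ratio, time-averaged MSD, direction autocorrelation, turning angles, fastest 25-µm segment; superplot (per-experiment) inference |
| `shape` | hand-drawn cell outlines | area, perimeter, moment-ellipse axes, mirror symmetry, solidity, extent, centroid distances |
| `assays` | invasion, liposome binding, cancer-genomics co-occurrence | depth-resolved invasion fraction (≥ 45 µm); densitometry correction with pelleting efficiency; 2×2 log2 odds ratio + Fisher p |
| `simulate` | all of the above | seeded generators: Gaussian-PSF punctum movies, mitochondrial masks, persistent-random-walk tracks, perturbed-ellipse contours, screen tables |

No external data are required: the synthetic-data module generates every
input with the statistical structure the estimators assume, and the test
suite uses it to verify closed forms, sampling laws, and parameter
recovery end to end.

## Worked example

A three-Rab capture screen with a planted strong hit (true corerouting
ratio 2.5 for Rab30), analyzed exactly like real screen data:

```r
library(invquant)

tab <- simulate_screen(
  constructs = "TPD54", rabs = c("GFP", "Rab30", "Rab11a"),
  true_ratio = matrix(c(1, 2.5, 1.2), 3, 1,
                      dimnames = list(c("GFP", "Rab30", "Rab11a"), "TPD54")),
  n_cells_per_condition = 20, seed = 42)
ratio <- tab$F_post / tab$F_pre

dunnett_vs_control(split(ratio, tab$rab), control = "GFP")
#>    group  n     mean      diff         t        p_adj significant
#> 1 Rab11a 20 1.257791 0.1972984  2.271135 4.965233e-02        TRUE
#> 2  Rab30 20 2.459084 1.3985912 16.099417 1.058043e-13        TRUE

bootstrap_bca_diff(ratio[tab$rab == "Rab30"], ratio[tab$rab == "GFP"],
                   n_boot = 1e4, seed = 42)
#> Mean difference: 1.399  [1.219, 1.584] (95% BCa, 10000 replications)
```

The planted ratio 2.5 is recovered as a mean F_post/F_pre of 2.46, a
difference of +1.40 over the GFP control with a tight BCa interval, and an
adjusted p ≈ 1e-13 — a clear hit; the weak Rab11a effect sits right at the
significance boundary.

Spatiotemporal variance separates vesicle-bound from static signal:

```r
mov <- simulate_vesicle_movie(n_puncta = 40, diffusion_coeff = 0.1,
                              frames = 30, frame_interval = 0.1775,
                              field_size = c(60, 60), seed = 1)
rois <- auto_select_rois(mov, n = 5, size = 20, brightness_band = c(5, 95),
                         seed = 1)
spatiotemporal_variance(mov, rois)
#> [1] 0.08920963
```

The identical scene frozen in place (`motile = FALSE`) scores 0.0016 — a
~50-fold separation driven purely by punctum motion.

The amplification co-occurrence statistic from a published 2×2 count table
(398 patients, 29 TPD54-amplified, 20 Rab25-amplified, 7 both):

```r
res <- cooccurrence_stats(398, 29, 20, 7)
res$log2_odds_ratio   #> 3.123217
res$fisher_p          #> 0.0002098
```

## Command line

Every analysis is also reachable through one CLI with seeded, reproducible
subcommands:

```sh
invquant simulate --what movie --config movie.cfg --seed 4 --out movie.tif
invquant stvar    --input movie.tif --roi-size 20 --n-roi 5 --seed 1 --out stvar.csv
invquant mito     --input post.tif --pixel-size 0.1 --min-area 0.2 --out mito.csv
invquant screen   --input screen.csv --control-label GFP --n-boot 100000 --seed 1 --out scr
invquant migrate  --input tracks.csv --segment-length 25 --out mig
invquant shape    --input contours.csv --out shape.csv
invquant invade   --input profile.csv --control siCtrl --out invasion.csv
invquant cooccur  --n-total 398 --n-a 29 --n-b 20 --n-ab 7
```

Track input accepts both the Fiji Manual Tracking export dialect and the
package's tidy format; movies are plain uncompressed grayscale TIFF.

## Documentation

`vignettes/invquant-methods.Rmd` describes the models and estimators, all
tunable parameters with units and defaults, the synthetic-data generators'
scope, and every numerical design decision (variance divisor, perimeter
estimator, symmetry definition, BCa construction, clustering defaults)
with its rationale.
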