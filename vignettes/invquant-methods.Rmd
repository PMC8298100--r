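---
title: "invquant: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{invquant: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invquant)
```

`invquant` is the quantitative layer of a live-cell trafficking workflow
built around intracellular nanovesicles (INVs): ~30-nm transport vesicles
marked by TPD52-like proteins. The package covers five measurement families
— spatiotemporal variance of fluorescence movies, mitochondrial aggregation
by circularity, vesicle-capture screen statistics, 2D migration track
statistics, and cell-shape descriptors — plus small assay quantifications,
all driven by a synthetic-data module so that every stage is testable
without microscope data. This vignette explains the models behind each
statistic, the tunable parameters and their defaults, and the numerical
decisions where the underlying protocol leaves the choice open.

## Spatiotemporal variance

A protein riding on fast-moving sub-resolution vesicles produces intensity
that flickers pixel-by-pixel; a diffuse cytoplasmic protein produces a
smooth, slowly varying field. The score separates the two regimes:

1. each frame is divided by its own mean intensity (removing global
   brightness drift and pool bleaching);
2. inside each region of interest (ROI), the temporal variance of every
   pixel is computed across the movie;
3. all pixel variances are pooled across ROIs and averaged, giving one
   scalar per cell.

Protocol conventions: 30-frame movies; five 20 × 20-px cytoplasmic excerpts
per cell for Rab-type movies (0.1775 s/frame) or one 50 × 50-px ROI for
FKBP-tagged constructs (0.3 s/frame). Both ROI sizes are defaults, not
constraints.

Numerical decisions, where the protocol is silent:

* **Sample variance (T − 1 divisor)**, the conventional unbiased estimator.
  At T = 30 the difference from the population variance is a uniform ~3.4%
  scale factor, irrelevant for the cross-construct comparisons the score is
  used for.
* **Whole-frame normalization**, the literal reading of "normalized to the
  mean pixel intensity for that frame" — not per-ROI normalization.
* **Pooled-pixel averaging** across ROIs, identical to the mean of per-ROI
  map means when ROIs share a size, and still well defined when they do not.
* Pixel indexing is 0-based and half-open throughout the ROI interfaces.

`auto_select_rois()` automates "excerpts positioned in the cytoplasm away
from bright structures": candidates on a non-overlapping grid qualify when
their mean time-averaged intensity falls inside a percentile band of the
first frame (default 25th–75th) and no pixel exceeds the band ceiling plus
1.5 band widths. The fence is Tukey's outlier rule; a hard cutoff at the
band ceiling itself would reject even pure-noise regions, because the
maximum of a few hundred pixels always exceeds the 75th percentile.
Manually placed ROIs are always honored in preference.

On a frozen scene with additive noise of standard deviation σ on the
normalized scale, the expected score is σ²; the test suite checks this
closed form, and checks that the score rises monotonically with the
simulated diffusion coefficient. The monotonicity test tiles the field with
ROIs (fixing the number of contributing puncta per movie) and sweeps D over
0.01–0.2 µm²/s. That range is a property of the readout, not a claim about
INV physics: at 0.1775 s/frame and 0.1 µm/px, per-frame displacements reach
~2.7 px at D = 0.2, about twice the PSF width, beyond which successive
frames decorrelate completely and the score saturates.

## Mitochondrial aggregation

Vesicle capture onto mitochondria collapses the tubular network into
blobs. From a single post-rapamycin image the package segments
mitochondria, measures per-object area A and perimeter P, and scores the
cell as the median circularity

$$ f_{circ} = \frac{4\pi A}{P^2} $$

over objects with area strictly greater than 0.2 µm². Circularity is 1 for
a circle, π/4 for a square, and approaches 0 for elongated tubules, so
higher medians mean stronger aggregation.

* **Threshold**: Otsu by default (parameter-free); an absolute threshold can
  be supplied. When the between-class variance is flat across an empty
  intensity valley, the threshold is placed mid-valley rather than at its
  edge.
* **Connectivity**: 8-connected foreground, so thin diagonal strands remain
  single objects.
* **Perimeter estimator**: the object boundary is traced at the 0.5 level of
  the binary mask (marching squares on the pixel-center lattice) and
  simplified with Ramer–Douglas–Peucker at 0.8 px tolerance before summing
  segment lengths. The motivation is accuracy on *both* ends of the shape
  spectrum: naive boundary-pixel counting overestimates circle perimeters by
  up to ~27% (pushing a disc's fcirc down to ~0.62), while Crofton-type
  intercept-count estimators are exact on discs but bias axis-aligned
  rectangles by ~5% low (pushing a square's fcirc ~11% high). The simplified
  mid-level boundary measures rasterized discs within ~2% and rectangles
  within ~3% for features larger than ~25 px; both pins are asserted in the
  tests against the closed forms.
* **fcirc is not clamped** at 1. Pixelation can push tiny near-circular
  objects slightly above 1; the 0.2 µm² filter removes most of them, and
  transparency is preferred over cosmetic clamping.

Because the original segmentation threshold and perimeter estimator are
unspecified upstream, absolute circularity values are estimator-dependent;
the supported contract is the *comparison* between conditions, which the
paired simulation test (aggregated vs network fields, 100/100 matched
seeds) exercises.

## Vesicle-capture screen statistics

Corerouting of a GFP-Rab with a mitochondrially trapped construct is
quantified per cell as F_post/F_pre: the mean mitochondrial pixel intensity
after rerouting divided by the mean before, pooled over ten 10 × 10-px
mitochondrial ROIs (a grand pixel mean — identical to averaging per-ROI
means at equal ROI sizes).

**Dunnett's many-to-one test.** Each Rab is compared against the
fluorophore control with pooled variance and single-step Dunnett
adjustment. No multivariate-t library is assumed: using the equicorrelated
representation of the Dunnett statistics (correlations λᵢλⱼ with
λᵢ = √(nᵢ/(nᵢ+n₀))), the family-wise CDF is a double integral over the
shared control variate and the pooled scale, evaluated with 128-node
Gauss–Legendre quadrature; the scale integral uses the exact scaled-chi
density. With a single comparison the adjusted p agrees with the
pooled-variance t-test to ~1e-13; the test suite also verifies family-wise
error 0.05 ± 0.01 under a 5000-replicate null simulation. Hits are called
at adjusted P < 0.05, with no additional FDR layer.

**Effect sizes.** Estimation statistics use the mean difference in ratio
against the control arm with a bias-corrected and accelerated (BCa)
bootstrap interval, default 10⁵ replications. The two arms are resampled
independently; the bias term z₀ comes from the fraction of bootstrap
statistics below the observed difference; the acceleration a is the pooled
per-arm jackknife skewness — the standard two-sample BCa construction,
which the upstream protocol (naming only the method and software) leaves
open. Degenerate bootstrap distributions collapse to a flagged point
interval. Coverage (95% ± 2%) is verified by simulation at n_boot = 10⁴.

**Screen matrix and clustering.** Per-cell ratios are averaged to a
Rab × construct matrix and standardized per column (each construct's screen
is one column; per-row and global standardization are available). Rab
profiles are clustered agglomeratively on Euclidean distances of the
Z-scores with complete linkage by default — the common default of the
heatmap stacks this kind of figure is drawn with — with average and Ward
options. Column standardization makes the clustering invariant to
per-screen affine rescaling of the raw ratios. Because the original
standardization axis and linkage are unstated, flat cluster counts (the
"how many INV populations" question) are reproducible only qualitatively;
`classify_inv_populations()` offers the complementary, assumption-light
view: each hit Rab is assigned to the subset of screens in which it was
significant (its Euler-set class).

## Migration track statistics

Tracks are timestamped 2D positions of cell nuclei (minutes, µm), typically
10-min sampling over 12 h. Per track: instantaneous and average speed,
cumulative path length, directionality ratio (net displacement over path
length), turning angles, and the fastest time to traverse a 25-µm path
segment. Per cohort: time-averaged mean squared displacement and direction
autocorrelation with means ± SEM across cells.

* **Overlapping windows** for MSD and autocorrelation (time-averaged
  estimators), the standard choice for short tracks; whether the original
  analysis overlapped intervals is unknown, so the per-track machinery keeps
  the choice localized.
* **Gaps are not interpolated**: steps spanning missing frames contribute to
  speed via their true Δt but are excluded from lag-based statistics.
* **Fastest-segment windows** are whole-step windows without sub-step
  interpolation, biasing the traversal time upward by at most one frame.
* **Turning angles** are step-to-step within a track, signed, in (−π, π].

The persistent random walk null: headings diffuse with correlation time P,
so the direction autocorrelation decays as exp(−lag/P) and is the estimator
the parameter-recovery tests invert (speed and P recovered within 20% over
a 3 × 3 parameter grid at 200 cells).

**Superplots.** Because cells within an experiment are not independent,
between-condition inference runs on per-experiment means: a two-sided
Student's t-test for two conditions (n = number of experiments), Dunnett
against a named control for more. A single experiment per condition is an
error (zero degrees of freedom), and an all-identical-means cohort returns
p = 1 rather than failing on zero variance.

## Shape descriptors

Cell outlines are simple closed polygons in µm, normalized counterclockwise
at ingest. Descriptors: shoelace area and perimeter; major/minor axis
lengths of the ellipse matching the exact area-weighted second central
moments of the polygon interior (length = 4√eigenvalue); aspect ratio
(minor/major); mirror symmetry; convex-hull area and solidity; bounding-box
extent; and extreme centroid-to-boundary distances.

* **"Cell center" is the area centroid** — rotation invariant, standard.
* **Symmetry** is read as overlap: the literal "cell area ÷ reflected
  footprint area" is identically 1 (reflection preserves area), so the
  implemented score is area(A ∩ reflect(A))/area(A), reflecting across the
  major axis through the centroid — the only non-degenerate reading
  consistent with a spread of observed values. A union variant
  (area(A)/area(A ∪ reflect(A)), related by union = 1/(2 − overlap) on a
  shared grid) is available behind a flag.
* **Polygon overlap by rasterization**: with no polygon-clipping library in
  the supported dependency set, both polygons are scanline-rasterized on a
  shared grid (longer bounding-box side = 400 px by default). On the shared
  grid a mirror-symmetric polygon reflects onto itself exactly, so symmetric
  shapes score exactly 1 and the discretization error (<1% for cell-sized
  outlines) only affects asymmetric overlaps.
* **Bounding box is axis-aligned** in the data frame, not the principal
  frame, so extent is orientation-dependent by construction.

## Synthetic data: what it emulates, what it does not

The generators produce data with the statistical structure the estimators
assume, each under a single explicitly seeded RNG (restored afterwards, so
simulation never perturbs the caller's stream):

* **Vesicle movies**: diffraction-limited puncta as pixel-sampled Gaussians
  (σ = 0.15 µm at 0.1 µm/px) doing Brownian walks with per-axis step SD
  √(2DΔt), periodic wrap (constant density over 30 frames), constant
  background, Gaussian read noise. Defaults follow the imaging protocol
  (30 frames, 0.3 s or 0.1775 s intervals); the diffusion coefficient and
  punctum density are free parameters — the upstream work does not
  characterize INV speed or density, and no value here is a claim about
  INV physics. No photobleaching, gain calibration, sub-pixel PSF
  integration, or 3D optics.
* **Mitochondrial masks**: "network" = thin curvilinear strokes (3 px wide,
  aspect ≥ 8), "aggregated" = separated discs, both with analytic ground
  truth. No realistic mitochondrial dynamics.
* **Tracks**: persistent random walk with per-experiment speed offsets and
  between-cell speed spread; the mean speed default (0.4 µm/min) matches
  reported control epithelial cells. Observed positions optionally carry
  tracking noise.
* **Contours**: perturbed ellipses r(θ) = r_ellipse(θ)(1 + Σ low-order
  Fourier terms), orders 2+; cosine terms preserve mirror symmetry about
  the major axis, sine terms break it and are scaled by the `asymmetry`
  parameter, so symmetry decreases monotonically in it on matched seeds.
  Self-intersecting draws are retried with damped perturbations.
* **Screens**: per-cell F_pre around a baseline (100 ± 10 a.u.), F_post =
  F_pre × (true ratio + N(0, cell noise)); planted corerouting effects of
  2.2–2.5 match the magnitude of strong reported hits.

A green test on synthetic data establishes that the estimators recover the
structure they assume, at the stated tolerances — not that real movies or
tracks satisfy those assumptions (real data add bleaching, drift, tracking
errors, heteroscedastic noise, and non-exponential persistence).

## Assay quantifications

* **Invasion**: fraction of total fluorescence at depths ≥ 45 µm
  (inclusive, per the stated threshold), over slices nominally 15 µm apart;
  normalized so the control-condition mean is exactly 1.
* **Liposome binding**: per lane, background and no-liposome (precipitation)
  control are subtracted, the result divided by the pelleting efficiency of
  that liposome diameter (measured relative to 100-nm liposomes and supplied
  as data — the efficiencies are read from gels, not printed constants), and
  normalized to wild type at 100 nm. Negative corrected densities clip to 0
  with a flag.
* **Co-occurrence**: from printed marginal counts the 2 × 2 table is
  reconstructed and summarized as the odds ratio (both × neither)/(A-only ×
  B-only), its log2, and a Fisher exact p — two-sided by default, since the
  upstream portal's sidedness is unstated; a flag switches it. Zero cells
  trigger the Haldane 0.5 correction, flagged.

## Worked example

```{r example}
tab <- simulate_screen(
  constructs = "TPD54", rabs = c("GFP", "Rab30", "Rab11a"),
  true_ratio = matrix(c(1, 2.5, 1.2), 3, 1,
                      dimnames = list(c("GFP", "Rab30", "Rab11a"), "TPD54")),
  n_cells_per_condition = 20, seed = 42)
ratio <- tab$F_post / tab$F_pre
dunnett_vs_control(split(ratio, tab$rab), control = "GFP")
bootstrap_bca_diff(ratio[tab$rab == "Rab30"], ratio[tab$rab == "GFP"],
                   n_boot = 1e4, seed = 42)
cooccurrence_stats(398, 29, 20, 7)[c("log2_odds_ratio", "fisher_p")]
```

## Known limitations

* Absolute circularity and symmetry values depend on the documented
  estimator choices; cross-condition comparisons are the supported use.
* The Dunnett implementation assumes normal within-group errors and a
  common variance (as the procedure itself does).
* The TIFF codec intentionally covers plain uncompressed grayscale stacks
  only — the formats the package itself writes plus common microscopy
  exports (8/16-bit unsigned, 32-bit float); compressed or multi-channel
  files are rejected with a clear error.
* Flat cluster counts from `cluster_screen()` depend on linkage and
  standardization choices and should be read qualitatively.
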