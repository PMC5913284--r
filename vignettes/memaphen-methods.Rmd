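---
title: "Quantifying microenvironment-imposed cell phenotypes on MEMA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microenvironment-imposed cell phenotypes on MEMA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memaphen)
```

## The scientific problem

Microenvironment microarrays (MEMA) print hundreds of combinatorial
microenvironments — an extracellular-matrix (ECM) "backbone" such as type I
collagen (COL1), type IV collagen (COL4), laminin-111 (LAM1) or a
LAM1+laminin-332 mix, optionally co-printed with one soluble factor
(osteopontin, IL-8, collagen VI α3, growth factors, cytokines, ...) — as a
grid of spots on one slide. Mammary epithelial cells are cultured on the
array, fixed, and stained for DNA and for two receptor tyrosine kinases, AXL
and cKIT, whose joint expression marks a plasticity- and drug-tolerance-
associated state. The analytical question is *which microenvironment
components push cells into the AXL+/cKIT+ state*, given that each spot mixes
two components and only a fraction of the cells on a spot respond.

`memaphen` implements the full analysis as a reusable, tested pipeline:

1. **design** — model of the combinatorial condition table and replicate
   spot layout;
2. **synthetic generator** — seeded spot images (or equivalent tables) with
   planted ground truth;
3. **imaging** — background-mode thresholding, subtraction, marker-based
   watershed segmentation, per-cell features;
4. **gating** — reference-condition thresholds, per-spot/per-condition
   AXL+/cKIT+ fractions;
5. **statistics** — binomial GLM decoupling of component effects, Tukey-type
   post-hoc contrasts, factor ranking, cell-line comparison;
6. **condition phenotype maps** — z-score hierarchical clustering and t-SNE;
7. **assay calculators** — 2^(−ΔΔCt) fold change, 4PL dose–response IC50,
   EdU proliferation fractions.

## The packaged 228-condition design

The study design this package models printed 228 unique combinations of 4
ECM backbones and 29 soluble factors (5–20 replicate spots each). The
published component lists do not determine the combinatorial rule that
produces exactly 228, so the packaged table (`default_design()`, also shipped
as `extdata/design_228_synthetic.csv`) is a declared *synthetic
reconstruction* reaching the printed total with the printed components: each
backbone alone (4), each backbone × each factor at its catalogued
concentration (4 × 29 = 116), and a 1:10 dilution block for the 27 factors
catalogued below matrix scale (4 × 27 = 108). Condition ids are
deterministic: sorted backbone names joined by `+`, a `|`, sorted factor
names, and an `@lo` tag for the dilution series. Any other design can be
supplied as a CSV or built with `enumerate_conditions()`.

## The synthetic generator: what it emulates

The generator is the package's source of ground truth; its defaults are the
study conditions every recovery test runs under, chosen once:

* **Subpopulation model.** A cell on a spot is double-positive with
  probability `pi = plogis(baseline_logit + sum of component effects)` —
  additive on the log-odds scale, which is exactly the structure the binomial
  GLM assumes. Defaults: baseline −2.5 (the suppressive COL4 reference holds
  ~8% double-positive cells), COL1 +1.6, LAM1 +1.5, LAM5 −0.25 (so the
  LAM1+LAM5 backbone nets +1.25), and positive soluble effects led by OPN
  (+0.9), IL-8 (+0.8) and COL6A3 (+0.7) with weaker TGFB/lumican/leptin/HA
  contributions — mirroring the qualitative ordering the pipeline is built to
  recover (COL4 suppressive; COL1 dominant; three leading factors).
* **Counts and placement.** Cells per spot are Poisson (default mean 25, a
  realistic density for a ~64 px spot at this magnification); centers are
  rejection-sampled inside the spot disk with minimum separation 2.2 nuclear
  radii, and an `overlap_fraction` knob deliberately plants touching pairs to
  exercise watershed splitting.
* **Intensities.** Marker intensities are lognormal per state (fluorescence
  is right-skewed): negative cells ~200 AU, positive cells ~1000–1200 AU,
  sdlog 0.35; DNA ~3000 AU. Images add a flat background (100 AU) and
  Gaussian noise (SD 10), are rounded, clipped to [0, 65535] and written as
  16-bit single-channel TIFFs named `{spot}_{channel}.tif`. Every level
  (spot, array, table) is seed-deterministic.

Three output granularities serve different stages: `render_array()` (pixels),
`simulate_cells()` (per-cell feature tables with the imaging stage's schema)
and `simulate_spot_counts()` (per-spot binomial counts). The coarser modes
carry the identical statistical structure without rasterization and are used
for full-array statistical work; pixel-level fidelity is validated separately
on the small rendered fixture. The generator does **not** emulate optical
PSFs, illumination gradients, autofluorescence, cytoplasm, or segmentation
artifacts of crowded tissue — so green tests demonstrate correctness of the
analysis chain under its stated model, not robustness to every pathology of
real microscopy.

## Imaging chain

**Background.** Each channel is thresholded at *twice the modal intensity* of
its histogram — the mode is taken as the background level — and the threshold
is subtracted with clipping at zero. Binning: if the image has ≤ `n_bins`
(256) distinct values the mode is the most frequent exact value; otherwise
256 equal-width bins over `[0, max]` with ties broken toward the lower bin
(conservative). All downstream intensities are on the background-subtracted
scale.

**Segmentation.** Marker-based watershed: markers are local maxima of the
Gaussian-smoothed (`sigma` = 2 px) corrected DNA channel, separated by at
least `min_distance` (default = expected nuclear radius, 4 px) and restricted
to the foreground mask (`corrected > 0`); the smoothed landscape is flooded
from the markers over the mask (`EBImage::propagate`), and objects under
`min_area` (15 px) are removed. One deliberate refinement: maxima are
detected on the `log1p`-transformed image. With per-cell lognormal
brightness, the raw-scale blur tail of a bright nucleus can swallow the peak
of a dim neighbor even at 2.2-radius separation; log stabilization removes
that brightness dominance (peak positions of isolated nuclei are unchanged)
and restores exact per-spot counts on the test fixtures. Callers may also
supply marker centers explicitly (`seed_centers`), the classical
marker-based mode when a second channel provides nuclei positions.

**Features.** Per retained label: pixel area, intensity-unweighted centroid
(0-based row/col everywhere), per-channel mean corrected intensity,
eccentricity of the second-moment ellipse, solidity, and neighbor count
(centroids within 3 × median equivalent radius by default). Solidity is
computed as pixel area over the number of lattice points inside the convex
hull of the label's pixels — in pixel-count units a convex region scores
exactly 1, avoiding the systematic under-estimate of continuous hull areas.
Labels under 3 px are dropped and counted, never silently.

## Gating

Positivity thresholds are learned from cells on *reference* spots — by
default conditions whose backbone is COL4 printed alone, the matrix the assay
treats as suppressive — as `mean + k·SD` per marker (sample SD; `k` = 1; at
least 50 reference cells enforced). Calls are strictly-above-threshold, so
ties resolve negative, and `double_pos` is the conjunction of both markers.
Spots aggregate to counts and fractions; conditions aggregate as unweighted
means over usable spots, with empty spots excluded *and counted*, and
data-free conditions kept as flagged rows. Whether gates should be refit per
slide or shared across a cell line's arrays is not determined by the source
material; the package fits one gate per supplied cell table, which
corresponds to per-array-run gating, and the selector, `k` and the reference
rule (`col4_alone` vs `col4_any`) are configuration.

## Component decoupling and post-hoc inference

Per-spot double-positive counts are modeled as binomial with a logit link:

    cbind(n_dp, n_cells − n_dp) ~ ecm_backbone + factor indicators

The backbone enters as a factor (reference level COL4); each soluble factor
enters as a presence indicator pooled over its concentration variants.
Because conditions mix components, the coefficients *decouple* each
component's additive log-odds contribution. A quasi-binomial dispersion
(Pearson χ²/df) is reported alongside the ML fit; on complete separation the
ML fit is refused with advice to use `method = "firth"`, a bias-reduced
(Jeffreys-prior penalized) IWLS implemented in the package.

Pairwise backbone contrasts use the single-step max-|z| adjustment over the
estimated multivariate-normal coefficient distribution (via `multcomp`) —
the standard generalization of Tukey's HSD to GLMs, since the exact
studentized-range law only applies to balanced Gaussian ANOVA. Contrast sign
convention is the package's own: `"COL1-COL4"` is the log-odds of COL1 minus
COL4, so positive means more double-positive than the reference; pairs are
enumerated alphabetically to mirror the conventional table layout. Factor
ranking applies the same adjustment to the factor coefficients
(present-vs-absent contrasts) and orders by estimate; factors observed on
fewer than 2 spots are excluded with a warning. `compare_lines()` offers two
documented statistics for between-line response divergence — the variance of
per-condition fraction differences, and a likelihood-ratio test for a
line × backbone interaction in the pooled GLM — because the original
"coefficient of variance" computation is not specified precisely enough to
reproduce as a single number.

## Condition phenotype maps

Each condition's phenotype vector holds, in fixed order: double-positive
fraction, subset and ungated mean AXL and cKIT intensities, cells per spot,
eccentricity and solidity. Conditions missing any feature are excluded with
a message. `zscore_cluster()` standardizes (columns by default; constant
features are dropped with a warning, an all-constant matrix errors),
clusters with Euclidean distance and average linkage, and pre-sorts rows by
condition id so leaf order is deterministic under input permutation. t-SNE
(`embed_conditions()`) standardizes features, initializes from the first two
principal components scaled to SD 1e-4, and runs exact (theta = 0) t-SNE for
1,000 iterations under the supplied seed — fully reproducible. Perplexity
defaults to 30 when the array is large enough (`n ≥ 3·perplexity + 1` is
enforced, with the error suggesting a feasible perplexity).

## Assay calculators

* `fold_change()` — ΔCt is gene Ct minus the arithmetic mean of the control
  genes' Ct within the sample; ΔΔCt subtracts the calibrator sample's ΔCt;
  fold = 2^(−ΔΔCt). The calibrator's folds are exactly 1 and folds are
  invariant to any constant Ct shift.
* `fit_4pl()` — least squares for `y = a + (b−a)/(1+(x/c)^d)`,
  parameterized in log-dose with starts `a = min(y)`, `b = max(y)`,
  `c = geometric-mean dose`, `d = 1` and a 3-start slope ladder on failure
  (Levenberg–Marquardt via `minpack.lm`). `c` is the IC50: `y(c) = (a+b)/2`
  identically; flat responses return a flagged degenerate fit rather than a
  spurious IC50. `paclitaxel_doses()` supplies the 5-point log ladder
  (0.001–1 µg/ml) used by the drug-tolerance design.
* `edu_tolerance()` — EdU+ percentage per replicate, condition means
  relative to a control condition (e.g. COL1 alone), and Welch t-tests of
  replicate percentages against the control.

## Orchestration and problem sizes

`run_pipeline()` chains the stages under one config and one seed, writing
every table as CSV plus a manifest of MD5 checksums; identical configs
reproduce identical checksums, a failing stage halts with its name and keeps
completed outputs, and dropped cells/spots are always counted in messages.
The package's validation runs use: the full 228-condition × 10-replicate
array in table mode for statistical recovery (≈ 57,000 cells), 200 replicate
fits for contrast recovery, 500 null replicates for family-wise calibration,
and an 18-spot rendered fixture for pixel-level segmentation fidelity —
sizes chosen to exercise the study-scale design while keeping a complete
validation run in the order of a minute. `make_fixture()` materializes the
`tiny` (rendered), `default` (table-level, full design) and `stress`
(rendered, 20 replicates) profiles. The exported functions are the
interface; there is no separate shell executable.

## Known limitations

* The 228-condition table is a reconstruction: totals and components match
  the printed design, the pairing rule is declared, not recovered.
* Positive fractions estimated through a `mean + k·SD` gate are attenuated
  when marker distributions overlap; recovery tests state their separation
  assumptions explicitly.
* The binomial GLM ignores spot-level overdispersion beyond reporting the
  quasi-binomial dispersion; a mixed-effects spot-in-slide model is out of
  scope.
* t-SNE coordinates are reproducible but, like all t-SNE output, not
  metrically meaningful beyond neighborhood structure.
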