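---
title: "Methods: compartment-resolved quantification in developing neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartment-resolved quantification in developing neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compartquant)
```

# Scope and model

`compartquant` re-implements, as a tested library, the quantification layer
of a high-content imaging study of developing human glutamatergic neurons:
synaptic and ribosomal puncta counted per subcellular compartment, local
protein synthesis (SUnSET) intensities, depolarization-evoked calcium
response features, compartment-separated proteome comparisons, and
gene-module expression scores, together with the statistical toolkit those
readouts feed. Every stage can be exercised on synthetic inputs whose ground
truth the generators record, so each operation is validated by parameter
recovery rather than by eye.

## Compartment ROIs

Four ROI classes are built from the DAPI and MAP2 channels:

* **Nuclei** — Otsu threshold, hole filling, distance-transform watershed to
  split touching nuclei, and an area gate in µm² (defaults 12–500 µm²).
* **Somata** — nucleus-seeded propagation through the *bright* MAP2 mask.
  The default soma threshold is a two-stage Otsu (a second Otsu split among
  the pixels above the global Otsu): somatic MAP2 staining is brighter and
  thicker than neuritic staining, and seeding the propagation into a mask
  that also contains neurites would let somata leak down the proximal
  processes. A radius cap (default 15 µm from the nucleus) bounds the soma
  even where the bright mask is large. Soma labels equal their seed nucleus
  labels, so the two maps correspond 1-to-1.
* **Neurites** — the thresholded MAP2 mask minus the soma mask, optionally
  ridge-enhanced first (single-scale Hessian tubeness, `ridge_filter()`),
  skeletonized by Zhang–Suen thinning. Total length is calibrated as
  orthogonal step = pixel size and diagonal step = √2 × pixel size, with
  corner-cutting diagonals not double-counted; endpoints are skeleton pixels
  of degree 1 outside somata. The thinning is implemented in the package;
  note the classic property of the parallel Zhang–Suen scheme that strokes
  only 2 px wide on the diagonal can vanish — thresholded neurite masks are
  ≥ 3 px wide, where the skeleton is stable (validated against generated
  polylines to within a few percent on constructed trees).
* **Whole cells** — connected components of the thresholded MAP2 signal; a
  component counts as a MAP2⁺ cell only when it contains a nucleus.

## Puncta detection, threshold, and the size gate

The intensity threshold is taken from negative-control wells (full staining
background, no specific signal): threshold = mean background intensity
+ *k*·SD with *k* = 0 by default, i.e. the plain background mean. Spot
*segmentation* needs a level above that mean (half of all background pixels
exceed it); footprints are therefore the pixels exceeding the threshold by
4 background SDs, with touching spots split by an intensity watershed
(tolerance 4 background SDs). Each footprint is summarized by centroid,
equivalent-circular diameter 2√(area/π), and mean intensity. A punctum is
retained iff its mean footprint intensity exceeds the threshold *and* its
diameter falls in the 0.4–4 µm gate — interpreted as equivalent-circular
diameter, the spot-analysis convention of high-content platforms. Retained
puncta are assigned to soma / neurite / whole-cell by centroid membership
(soma taking precedence over neurite over plain cell membership); centroid
assignment was chosen over majority-footprint as the simpler rule with
identical behaviour on well-formed spots.

Colocalization overlays channel A onto channel B: the overlap fraction of an
A punctum is the share of its footprint pixels covered by *any* B footprint,
and the punctum is colocalized when the fraction is at least the cutoff
(default 0.5, with the tie at exactly 0.5 counting). An A punctum
overlapping several B puncta counts once — the readout is colocalized
puncta, not pairs.

## Normalization formulas

Per well and channel, puncta counts (PC) become densities:
ΔPC = PC/somata count (somatic), PC/MAP2⁺ cell count (whole-cell), or
PC/total neurite length in µm (neuritic). Fold changes are plate-matched:
ΔΔPC = ΔPC / ΔPC of the wild-type reference on the same plate, where
several wild-type reference wells enter through their mean. The identical
pattern gives ΔMI = MI/MI(wild type, same plate) for SUnSET mean
intensities (the ratio is taken on raw mean intensities, without background
subtraction), ΔID = ID/ID(housekeeping) and ΔΔID = ΔID/ΔID(wild type, same
membrane) for blot densitometry, and for qPCR
ΔCt = Ct(target) − mean(housekeeping Cts) over the three housekeeping genes
(arithmetic mean of Cts = geometric mean of expression; the combination rule
is not otherwise specified), ΔΔCt relative to the reference condition, and
log₁₀(2^−ΔΔCt) as the reported scale. Zero denominators flag the record
missing — excluded listwise at the statistics stage, never imputed or
divided through. Technical wells are averaged per (clone, biological
replicate) before any statistics, so the group tests never see
pseudo-replicates.

## Calcium features

Traces are baseline-normalized per ROI, ΔF/F₀ with F₀ the mean prestimulus
fluorescence; the baseline window defaults to everything up to 1 s before
stimulus onset (only "prestimulus" is prescribed; the margin keeps the
stimulus artifact out of the baseline). Onset, when
not supplied, is the time of the maximal first difference of the cross-ROI
mean trace, ties to the earliest frame. Within the 0–20 s poststimulus
window the features are: peak ΔF/F₀ (maximum), baseline-subtracted AUC
(trapezoidal integral of the series minus the baseline mean), peak latency,
and the 10–90% rise time on the rising limb before the peak with linear
interpolation between frames. A flat trace reports peak 0, AUC 0 and
latency 0 with a quality flag rather than NAs, so downstream arithmetic
stays defined; a non-positive peak leaves the rise time missing. An ROI is a
responder iff peak > baseline mean + 3 × baseline SD, strictly; baseline SD
is computed on the raw (unsmoothed) ΔF/F₀ baseline frames. Group
comparisons are two-sided Wilcoxon rank-sum tests treating ROIs as
independent observations, exact for untied samples of ≤ 25 per group.

## Proteomics

Starting from a proteins × samples matrix of log2 LFQ intensities with
explicit missingness: the detection filter retains proteins observed in at
least 70% of the (post-exclusion) samples and is idempotent;
compartment-exclusive sets are computed on the *unfiltered* table (≥ 1
detection in one compartment, 0 in the other), matching the order used for
the control-line analysis, though the functions compose in either order.
The neurite-vs-soma comparison is an ordinary per-protein two-sample
pooled-variance t test with Benjamini–Hochberg adjustment — a deliberate
approximation of moderated statistics that is validated on synthetic data
and cross-checked against `limma` in the test suite; a protein passes at
adjusted p < 0.05 and |log2FC| > 1.5. Abundance ratios divide the soma
log2 LFQ value by the matched neurite value within a replicate — a ratio of
logs, by design — not a log of ratios — with a difference-of-logs column
emitted alongside for interpretability.

## Gene modules

Each member gene is z-scored across samples (n − 1 denominator); a module
score is the per-sample mean of member z-scores, hence exactly zero-sum
across samples. Genes are standardized across samples (not within samples):
per-sample standardization would erase the genotype contrasts the scores
exist to measure. Missing module genes are dropped with a warning once more
than half the module is absent; zero-variance genes are excluded.

## Statistics

Shapiro–Wilk gates every group at α = 0.05; any failing (or unassessable,
n < 3 or degenerate) group routes the analysis to the nonparametric branch.
Parametric: one-way/multi-way ANOVA (sequential main effects on balanced
designs, no interactions) with Tukey HSD and η² = SS_between/SS_total.
Nonparametric: tie-corrected Kruskal–Wallis with η²_H = (H − k + 1)/(n − k)
and Dunn's z on mean ranks with Holm step-down adjustment. Gene-set overlap
uses the 2×2 table {a, A−a, B−a, N−A−B+a} against a user-supplied
background N (never inferable from the data), reporting the sample odds
ratio ad/bc and the two-sided exact p. Bootstrap estimation resamples
within groups with replacement and reports percentile intervals,
deterministic under seed.

# Synthetic data: what it emulates, and what it does not

**Plates.** Each well holds one or more fields of four channels. Nuclei are
disks, somata larger disks, neurites persistent-direction random-walk trees
rooted at the soma edge with per-step branching; polyline lengths are
recorded exactly. Puncta counts are Poisson — neurite counts with mean
density × length/100, soma and whole-cell counts per unit — placed on the
recorded compartment masks, with per-genotype density multipliers. Spots are
2D isotropic Gaussians whose σ is solved so that the above-segmentation-level
footprint has the sampled equivalent-circular diameter; that diameter is what
the ground truth records, making the size-gate tests self-consistent.
Negative-control wells carry the full background model and the structure
channels but no puncta-channel signal — the operational reading of
secondary-antibody-only control wells. The generator does *not* model 3D
stacks, PSF realism, photobleaching, spectral bleed-through, uneven
illumination, or cell-to-cell intensity variation; passing tests therefore
demonstrate correctness of the measurement logic, not robustness to every
artifact of real microscopy.

**Calcium.** The transient kernel is a difference of exponentials
normalized to unit peak (no kernel is specified by the source; this is the
standard minimal shape), so the configured amplitude *is* the true peak
ΔF/F₀; amplitudes are normal truncated at 0, and Gaussian noise is added in
ΔF/F₀ units. The `"d7_kcl"` preset uses 4 ROIs per group — the emulated
experiment's exact rank-sum p of 0.029 is the two-sided minimum 2/70,
attainable only at 4 vs 4 — with group peak means 1.222 and 1.383 and SDs
back-computed from the mean ± SEM at that n; the mutant decay constant (6 s vs 1 s) encodes the
reported prolonged responses. Acquisition noise statistics are free
parameters (noise SD 0.02 ΔF/F₀ at 20 Hz by default).

**LFQ.** Log2 abundances are normal around per-protein baselines with
compartment/genotype shifts; non-detection is logistic in log2 abundance
(left-censoring, the dominant DIA mechanism), which is what makes the 70%
filter a meaningful operation. Planted exclusives are structurally missing
in the opposite compartment; planted differential proteins carry a
configured log2 shift.

**Expression.** I.i.d. standard-normal baselines with additive per-module
group shifts in SD units. A planted +1 SD shift reappears in module scores
attenuated by 1/√1.25, because the shift itself inflates the cross-sample
variance used for z-scoring — the tests assert that analytic factor.

# Numerical choices and problem sizes

Thresholds are configurable everywhere with Otsu defaults; coordinates are
0-based row-major in the mask convention, with centroids reported on the
pixel grid. Watershed tolerances (nucleus splitting: 1 on the distance map;
spot splitting: 4 background SDs) trade over- against under-segmentation and
are exposed as arguments. Detection's two-point resolution is ≈ 1 µm at the
default optics (0.3 µm pixels, 0.6–1.6 µm spots): closer spot pairs merge.
The fold-change recovery experiment (`ddpc_recovery_experiment()`) therefore
uses 1.25 neurite puncta/100 µm at multiplier 1 with 0.6–1.0 µm spots, so
that overlap losses stay below ~2% even at a 4× multiplier; its plates have
2 reference and 2 mutant wells of 2 fields each plus a negative control, and
20 plates per multiplier — enough for a standard error of ~2–4% on the
recovered mean ΔΔPC. Simulation-backed tests elsewhere use 60–200 replicate
seeds and 3-standard-error tolerances; the type-I-error suite uses 2,000
null simulations per test.

# Known limitations

* Skeleton length underestimates true arbor length by roughly 15–20% on
  rendered trees (soma-exclusion zone, boundary clipping, staircase
  shortcuts); the bias is genotype-independent and cancels in plate-matched
  fold changes, which is the quantity the pipeline reports.
* The ordinary-t proteome comparison is slightly conservative relative to
  moderated statistics at n = 6 per compartment; effects near the
  significance boundary can differ from a `limma` analysis.
* Compartment assignment is by centroid: a punctum straddling the
  soma–neurite border contributes to exactly one compartment.
* `multiway_anova_main_effects` reports sequential main effects and is
  intended for balanced or near-balanced designs only.
* The whole-cell puncta process scatters spots uniformly over the cell mask;
  real whole-cell counts are the union of compartment-specific biology, so
  whole-cell densities should be read as calibration scaffolding, not as a
  biological model.
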