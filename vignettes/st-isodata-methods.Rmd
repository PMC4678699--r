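---
title: "Spatiotemporal ISODATA tissue signatures: models, parameters, and design choices"
author: "stisodata authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal ISODATA tissue signatures: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stisodata)
```

## The problem

After an ischemic stroke, brain tissue does not evolve uniformly: some
regions are irreversibly infarcted within the first hour, others are
recruited into the lesion over days, others swell transiently and recover.
Serial quantitative MRI observes this as coupled trajectories of the
apparent diffusion coefficient (ADC, mm²/s, which drops acutely with
cytotoxic edema), fractional anisotropy (FA, unitless, which degrades as
tissue microstructure breaks down), and the transverse relaxation time
(T2, ms, which rises with vasogenic edema). `stisodata` clusters voxels by
their *joint spatiotemporal* trajectory across all timepoints and all
parameters at once, so that each cluster is a "tissue signature": one
characteristic way tissue evolves after the insult.

The package implements the full chain: preprocessing of co-registered
serial maps, an ISODATA clustering core with Mahalanobis assignment and
data-driven splitting/merging, coefficient-of-variation (CoV) pruning of
temporally flat clusters, normalization of cluster values onto a 1–100
scale anchored at contralateral white matter (WM) and CSF, binning into
named signatures, operational tissue classification from lesion masks, and
Dice-based evaluation. Because serial multiparametric primate stroke data
are not generally available, the package ships a synthetic phantom
generator that reproduces the *structure* of such a study with known ground
truth; it is first-class, tested code, and every pipeline stage is
validated against it.

## Preprocessing model

**Analysis mask.** Voxels whose first-timepoint ADC exceeds
1.2×10⁻³ mm²/s are excluded before clustering (strict inequality); such
values arise almost exclusively from CSF and large vessels. The exclusion
is applied before relative-map computation so that contralateral means are
parenchymal means.

**Relative maps.** Each map is divided by its mean over the contralateral
hemisphere restricted to the analysis mask, giving rADC/rFA/rT2 maps in
which healthy tissue sits near 1 regardless of scanner scaling. The package
tracks relative maps explicitly and refuses to renormalize them a second
time. Whether the divisor should be the masked or the whole-hemisphere mean
is genuinely open; the masked mean was chosen because it is robust to the
(excluded) ventricles.

**Spatial contiguity weighting.** Before features are assembled, every
in-mask voxel of every relative map is replaced by the Gaussian
distance-weighted mean of its in-mask neighborhood:
`w(d) = exp(-d²/(2·decay²))` with `d` the Euclidean distance in voxel
units, zero weight for out-of-mask neighbors, and weights renormalized to
one. Defaults are `radius = 1` (a 3×3×3 neighborhood) and `decay = 1.0`.
This is the "spatial" part of ST-ISODATA: it damps voxel noise at the cost
of mild blurring at compartment interfaces. Because the center voxel always
carries weight 1, isolated voxels pass through unchanged (with a warning).

**Feature matrix.** One row per analysis-mask voxel, columns ordered
timepoint-major (`t₁p₁, t₁p₂, …, t₂p₁, …`) over the selected parameter
combination; with 7 timepoints and 3 parameters, 21 columns. Columns are
z-scored by default and the (mean, sd) pairs recorded in the matrix; this
makes Mahalanobis distances with a diagonal global covariance well scaled
across parameters with different units, and lets downstream stages map
centroids back to interpretable relative values.

## The ISODATA core

ISODATA is k-means with a variable cluster count: clusters that are too
dispersed are split, clusters that are too close are merged, and clusters
that are too small are discarded. The controls are:

| control | meaning | default |
|---|---|---|
| `phi_N` | minimum voxels per cluster | 100 |
| `phi_C` | minimum inter-centroid Mahalanobis distance | derived: WM–GM distance |
| `phi_S` | maximum intra-cluster dispersion | derived: pooled WM sd |
| `k` | initial cluster count | 6 |
| `K` | cluster-range anchor | 8 |
| `I` | iteration cap | 100 |
| `eps_r` | convergence threshold | 10⁻⁴ |
| `L` | merges per merging iteration | 1 |

`phi_C` is derived as the Mahalanobis distance between the mean
contralateral-WM and mean contralateral-GM feature vectors — two clusters
closer than two healthy tissue types are not worth distinguishing.
`phi_S` is the population standard deviation of all WM-voxel feature
values pooled over every column. These two quantities live on slightly
different scales (a distance vs. a standard deviation); standardizing the
features keeps them commensurate, and both are recomputed per study and
per parameter combination.

The live cluster count is confined to the integers strictly inside
`(0.5K, 2K + 1)` — with the default `K = 8`, between 5 and 16.

**Covariance.** All Mahalanobis computations use a single global diagonal
covariance estimated from all analysis-mask rows (essentially the identity
after standardization), regularized by adding 10⁻⁶ of the mean diagonal.
A global diagonal keeps centroid–centroid distances symmetric and cheap;
per-cluster covariances would make `D_inter` ill-defined.

**Initialization.** The first centroid is a uniformly drawn data row. Each
later centroid is chosen by drawing `u ~ U(0,1)` and walking the candidate
rows until the running sum of their summed distances to the already-chosen
centroids first exceeds `u` times the total — rows far from existing
centroids are preferred in proportion to their distance. A single seeded
generator is threaded through the run and recorded in the model.

**Iteration.** Each iteration assigns every row to its nearest centroid
(ties to the lowest id), discards clusters below `phi_N` (their rows move
to the nearest surviving centroid), computes per-cluster `D_intra` (mean
member-to-centroid distance) and pairwise `D_inter`, and then either
splits or merges: odd iterations split the single worst cluster with
`D_intra > phi_S` into `mu ± 0.5·sigma_max·e_max` along its
largest-variance axis (skipped if the count would leave the allowed range
or a child would fall below `phi_N`); even iterations merge the closest
pair with `D_inter < phi_C`, at most `L` times, never below the range's
lower bound. Alternating by parity is the classic way to keep the two
forces from fighting within one iteration. Convergence is declared when an
iteration makes no structural change and the maximum relative centroid
displacement `‖µ_new − µ_old‖ / (‖µ_old‖ + 10⁻¹²)` falls below `eps_r`.

**A note on limit cycles.** When the derived `phi_C` is larger than some
genuine inter-cluster distances (it often is, because WM and GM differ
strongly in FA), a high-dispersion cluster can be split on an odd
iteration and its children re-merged on the next even one, indefinitely.
The voxel partition is stable throughout; only the nominal cluster count
oscillates by one. The iteration cap `I` bounds the cost, the log records
every event, and hitting the cap is reported (`converged = FALSE`), not
treated as an error. With splitting, merging, and discard disabled
(`phi_S = Inf`, tiny `phi_C`, `phi_N = 1`) the loop reduces exactly to
Lloyd's algorithm, which the test suite verifies against an independent
oracle.

## Pruning, normalization, binning

**CoV pruning.** A signature is only interesting if it *changes* over
time. For each cluster the centroid is mapped back to relative units and,
per parameter, the temporal coefficient of variation (population sd over
timepoints divided by the mean) is computed; the pooled CoV is the maximum
over parameters, so a cluster dispersed in any single parameter counts as
dispersed. Clusters at or below the threshold (default 0.05) merge into a
single normal-tissue cluster (union of voxels, size-weighted centroid).
Healthy WM and GM are time-constant and collapse into "normal" regardless
of how the clustering subdivided them; the abnormal clusters survive.

**Normalization.** Cluster identities are arbitrary across runs and
datasets, so retained clusters are projected onto a reproducible 1–100
scale: each centroid is scored by its relative proximity
`s = ‖µ − wm‖ / (‖µ − wm‖ + ‖µ − csf‖)` to reference feature vectors
for contralateral WM and CSF, and the scores are affinely rescaled so the
WM-nearest cluster maps to 1 and the CSF-nearest to 100. Because
high-ADC voxels were excluded before clustering, no CSF *cluster* exists;
the CSF anchor is therefore computed directly from the CSF reference ROI
on the (unmasked) relative maps and standardized with the feature matrix's
recorded column statistics, preserving the anchor semantics without
re-including CSF voxels. The scale is invariant to joint affine
transformations of centroids and anchors.

**Binning.** Normalized values are cut into tens-bins with closed upper
bounds: values at or below 5 are Signature N (normal); 6–15 is Signature
I, 26–35 II, 36–45 III, 46–55 IV, 56–65 V; the remaining tens ranges
(16–25 and 66–100) carry generic labels B2 and B7–B10 — bins that exist on
the scale but carried no named signature in the motivating study.

## Tissue classes and evaluation

Lesion ROIs — the acute (1-h ADC) lesion, the chronic follow-up T2 lesion,
and the maximal lesion (the timepoint of largest T2 lesion extent) — are
dilated with three 6-connected 3D dilation passes (26-connectivity is
available; 6 is the most conservative growth) and combined by set algebra:
Core = acute ∩ chronic, Growth = chronic \ acute, Recovery = acute \
chronic, Edema = maximal \ (acute ∪ chronic), Normal = everything else in
the brain mask. Acute membership takes precedence, so an
acute-and-maximal-but-not-chronic voxel is Recovery, not Edema. All three
ROIs are dilated uniformly before classification; passing raw masks opts
out.

Segmentation quality is the Dice similarity index
`DSI = 2TP/(2TP + FP + FN)` between the pruned abnormal region and the
maximal-lesion ROI, evaluated inside the ipsilateral analysis mask (the
signature analysis is restricted to the ipsilateral parenchyma, so the
overlap is too). When both masks are empty in the region the DSI is
defined as 1, and the event is logged. `sweep_configurations()` evaluates
the six parameter combinations (ADC, FA, T2, ADC+FA, ADC+T2, ADC+FA+T2)
against CoV thresholds from 0.10 down to 0.01; clustering is performed
once per combination and re-pruned per threshold, which is exactly
equivalent to independent runs because pruning is pure post-processing of
the fitted model. Per-configuration seeds are derived from the master seed
and the combination label, so results do not depend on grid order.

## The synthetic phantom

`generate_phantom()` builds an ellipsoidal brain (default 64×64×24 voxels
of 2 mm): a WM interior, a GM shell occupying the outer 20 % of the brain
radius, and a central ventricular CSF compartment whose ADC
(3.0×10⁻³ mm²/s) sits above the exclusion threshold by construction.
Default baselines (WM 0.70×10⁻³ mm²/s / 0.45 / 80 ms; GM 0.80×10⁻³ /
0.15 / 95 ms; CSF 3.0×10⁻³ / 0.05 / 2000 ms) are physiologically typical
configuration values, not measurements. Hemispheres split at the
mid-sagittal plane; the left (low-x) half is ipsilateral by convention.
Coordinates are 0-based voxel indices.

Ellipsoidal lesion regions in the ipsilateral WM carry signature-specific
relative time-courses: every voxel's value is `baseline × multiplier +
Gaussian noise`, with the default noise sd set to 5 % of the WM baseline
per parameter, FA clipped to [0,1] and ADC/T2 to non-negative values. The
default profile table is piecewise-linear in log-time through anchors
chosen to encode the qualitative signature behaviors (the acute ADC drop
deepest for V then II, the 24-h ADC rebound of IV, the monotone T2 rise of
II and V, the 144-h T2 peak of I and IV, acute FA loss only in V, and so
on); the anchor table in `default_signature_profiles()` documents each
constraint. Multipliers apply to parenchymal voxels only — a region
grazing the ventricles does not relabel CSF.

Ground truth comes from the noiseless data: the acute ROI is where the
noiseless 1-h rADC falls below 0.9; the chronic ROI where the noiseless
final rT2 exceeds 1.3; the maximal ROI is the abnormal extent at the
earliest timepoint where that extent is largest. The rT2 threshold sits
above the GM relative level (≈1.09) so healthy GM is never flagged — with
a GM shell present the contralateral mean is a WM/GM mixture, so relative
levels of pure compartments are not exactly 1. The default three regions
(II, IV, V) yield Core (II, V — acutely and chronically abnormal) and
Recovery (IV — its T2 renormalizes by the final timepoint); configs with
regions I and III add Edema and Growth. Truth tissue classes are computed
from the undilated truth ROIs, and `truth_clusters` records the generative
mixture component of every voxel (WM, GM, CSF, or signature), which is the
correct reference for judging cluster recovery.

**What the phantom does not emulate:** registration error, motion, bias
fields, partial-volume gradients, anatomical detail beyond three
compartments, spatially correlated noise, or k-space acquisition physics.
Tests passing on the phantom therefore demonstrate algorithmic
correctness — recovery of planted structure under additive noise — not
performance on real scanner data.

## Numerical choices and degenerate inputs

* Population (1/n) standard deviations for `phi_S` and temporal CoV.
* Ties break toward the lowest index everywhere (assignment, merge pairs,
  maximal-ROI timepoint).
* Zero-variance feature columns get sd 1 during standardization instead of
  dividing by zero.
* The global diagonal covariance is regularized with 10⁻⁶ of its mean
  diagonal; an all-zero covariance is an error.
* A cluster whose trajectory mean is zero has no defined CoV and errors
  out (impossible for relative maps, which are positive).
* All clusters below `phi_N`, or an empty contralateral region, or
  coincident WM/CSF anchors abort with explicit errors.
* Problem sizes: the shipped checks run the full pipeline at the default
  64×64×24 grid (≈37k analysis voxels) and the 60-configuration sweep at
  32×32×16, sizes chosen so the whole suite completes in a few minutes on
  one core while keeping every region comfortably above `phi_N`. At the
  reduced grid the planted regions shrink to ≈30–60 voxels, so sweeps
  there use `phi_N = 20`, mirroring how the minimum cluster size must
  scale with resolution.

## Known limitations

* The split/merge limit cycle described above means `converged = FALSE`
  is common with a large derived `phi_C`; interpret it together with the
  iteration log, not as a failure.
* The normalization stretches the retained clusters across the full
  1–100 range by construction (the CSF-nearest cluster always maps
  to 100); with very few retained clusters the bin labels are coarse.
* CoV pruning measures only *temporal* dispersion of the centroid; a
  spatially artefactual but temporally varying cluster will survive it.
* The pipeline assumes co-registered, skull-stripped inputs; no
  registration, eddy-current correction, or brain extraction is provided.
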