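# stisodata

Spatiotemporal ISODATA tissue signatures for serial stroke MRI.

## What this is for

After an ischemic stroke, tissue fate is heterogeneous: some regions
infarct within the first hour, others are recruited into the lesion over
days, others swell and recover. Serial quantitative MRI sees this as
per-voxel trajectories of the apparent diffusion coefficient (ADC, mm²/s),
fractional anisotropy (FA) and quantitative T2 (ms). `stisodata` is for
researchers analyzing such serial, co-registered, skull-stripped
multiparametric studies (experimental stroke models or comparable serial
designs) who want an *unsupervised* decomposition of the brain into
temporal "tissue signatures" — clusters of voxels sharing one
characteristic ADC/FA/T2 evolution — plus the downstream summaries:
operational tissue classes (Core / Growth / Recovery / Edema), per-signature
temporal profiles, and Dice-based evaluation against reference lesions.

## The method

Voxels inside the analysis mask (brain minus voxels with first-timepoint
ADC > 1.2×10⁻³ mm²/s, i.e. CSF and vessels) are described by a t×f feature
vector: f relative parameters (rADC, rFA, rT2 — each map divided by its
mean contralateral value) at t timepoints, spatially regularized by a
Gaussian-weighted neighborhood mean and z-scored per column.

Clustering is ISODATA — k-means with a data-driven cluster count. Voxels
are assigned to the centroid µ_j with the smallest Mahalanobis distance
(global diagonal covariance). Clusters with fewer than Φ_N voxels are
discarded; a cluster whose mean member–centroid distance D_intra exceeds
Φ_S is split; centroid pairs closer than Φ_C are merged (≤ L per
iteration); the count stays strictly inside (0.5K, 2K+1). Φ_C is derived
as the Mahalanobis distance between contralateral WM and GM, Φ_S as the
pooled standard deviation of WM feature values. Defaults: Φ_N = 100,
k = 6, K = 8, I = 100, ε_r = 10⁻⁴, L = 1.

Fitted clusters are pruned by temporal coefficient of variation (clusters
with pooled CoV ≤ 0.05 merge into a single "normal" cluster), projected
onto a 1–100 scale anchored at contralateral WM (→1) and CSF (→100), and
binned in tens: N (≤5), I (6–15), II (26–35), III (36–45), IV (46–55),
V (56–65), with generic labels for the remaining ranges. Tissue classes
come from set algebra on dilated lesion ROIs (Core = acute ∩ chronic,
Growth = chronic∖acute, Recovery = acute∖chronic, Edema = maximal only),
and segmentations are scored with the Dice similarity index
DSI = 2TP/(2TP+FP+FN). `sweep_configurations()` ranks the six input
combinations (ADC, FA, T2, ADC+FA, ADC+T2, ADC+FA+T2) across CoV
thresholds 0.10…0.01.

A synthetic phantom generator (`generate_phantom()`) produces serial
studies with a WM/GM/CSF anatomy, planted lesion signatures with known
time-courses, additive Gaussian noise, and full ground truth (labels,
lesion ROIs, tissue classes), so the whole pipeline is testable without
imaging data. See the methods vignette
(`vignettes/st-isodata-methods.Rmd`) for the model, parameter rationale,
and limitations.

## Worked example

```r
library(stisodata)

phantom <- generate_phantom(phantom_config())   # default 64x64x24 study
phantom
#> phantom_dataset: 64x64x24 grid; 813 lesion voxels in 3 region(s)
#> serial_study: 64x64x24 grid, 7 timepoints ( 1, 2, 3, 24, 72, 144, 240 h ), parameters: ADC, FA, T2
#>   brain voxels: 37824

run <- run_pipeline(phantom$study, out_dir = "stroke_run", seed = 1)
run
#> pipeline_run (ADC+FA+T2): 5 clusters -> 4 after CoV pruning (threshold 0.05); DSI vs maximal lesion = 0.973
```

The clustering found 5 clusters (healthy WM, healthy GM, and the three
planted lesion regions); CoV pruning merged the two time-constant healthy
clusters into one normal cluster, leaving 4. The pruned abnormal region
overlaps the ground-truth maximal lesion with DSI 0.973. Per-signature
temporal profiles recover the planted time-courses:

```r
head(subset(run$profiles, parameter == "rADC" & signature != "N"), 4)
#>    signature timepoint_h parameter      mean         sd   n
#> 22       III           1      rADC 0.7874769 0.03459427 305
#> 25       III           2      rADC 0.7983570 0.03134301 305
#> 28       III           3      rADC 0.8211768 0.02723639 305
#> 31       III          24      rADC 1.0439696 0.02601213 305
```

This bin (values 36–45 on the normalized scale) is the planted "acute ADC
drop with 24-h rebound" region: rADC ≈ 0.79 at 1 h recovering past 1.0 by
24 h. Bin labels are positions on the WM→CSF scale, not identities of the
planted regions. The signature-by-class cross-tabulation shows it lands
almost entirely in Recovery tissue, as planted:

```r
run$crosstab[run$crosstab$n > 0, ]
#>    signature    class     n pct_of_signature
#> 8          N   Normal 15612       87.2227499
#> 4          N     Core  1449        8.0954243
#> 12         N Recovery   838        4.6818258
#> 2        III     Core     2        0.6557377
#> 10       III Recovery   303       99.3442623
#> 3         IV     Core   367      100.0000000
#> 1        B10     Core   161      100.0000000
```

(The Core/Recovery voxels under signature N are the 3-step ROI dilation
reaching beyond the actual lesion.) `stroke_run/` now contains the cluster,
signature, and class volumes as NIfTI, the profiles and cross-tab as CSV,
and a byte-reproducible `summary.json`.

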