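# voxcord

Voxel-wise concordance analysis of co-registered multi-modal brain tumor
imaging: dual-tracer PET (a TSPO ligand and an amino-acid tracer) against
contrast-enhanced T1-weighted MRI.

## The problem

In gliomas it matters whether a PET signal reflects specific tracer
binding or merely leakage through a disrupted blood–brain barrier (BBB).
Comparing where and how strongly each modality lights up — voxel by voxel,
not per whole-tumor summary — separates the two: if PET uptake were driven
by BBB breakdown, PET intensity should track contrast enhancement both in
value and in location. `voxcord` implements that comparison as a tested
pipeline for anyone working with co-registered 3D scalar volumes
(NIfTI-1), and ships a synthetic phantom generator with programmable
ground truth so every stage can be validated without patient data.

## The method

Given co-registered volumes on one grid:

1. **Normalization.** PET volumes become tumor-to-background ratio images,
   TBR(v) = I(v) / mean(I over a healthy contralesional background VOI).
   MRI becomes relative contrast enhancement,
   rCE(v) = (CE(v)/BG_CE) / (T1(v)/BG_T1), a surrogate for BBB leakage
   under the linear contrast–concentration assumption. Near-zero T1
   denominators are excluded, never propagated.
2. **Segmentation.** Seeded iso-contour region growing inside a confining
   mask: all connected voxels with value ≥ threshold. Default thresholds:
   TBR_FET 1.6 (biopsy-validated biological tumor volume), TBR_GE180 1.8,
   rCE and TBR_T2 1.3. The analysis volume is the union of all modality
   segmentations (T2 contributes voxels only; it joins no correlation).
3. **Hotspots.** The hottest N connected voxels grown greedily from the
   maximal voxel of each segmentation, with N from an equivalent-sphere
   diameter: N = round((π/6)·d³ / (sx·sy·sz)); d = 10 mm at
   2.036 × 2.036 × 2.027 mm voxels gives N = 62.
4. **Concordance statistics**, per modality pair (TBR_GE180 vs rCE,
   TBR_FET vs rCE, TBR_GE180 vs TBR_FET):
   - Pearson r with OLS slope/intercept over the analysis volume, with
     strength classes (|r| ≤ 0.3 none/very weak, ≤ 0.5 weak, ≤ 0.7
     moderate, > 0.7 strong) and significance stars;
   - quadrant classification of every analysis voxel (in both
     segmentations / first only / second only / neither);
   - Dice coefficient D = 2|V1∩V2| / (|V1|+|V2|) of the hotspots;
   - symmetric average Hausdorff distance
     AHD = max(dAHD(V1,V2), dAHD(V2,V1)), where dAHD is the mean
     nearest-point distance in mm;
   - sub-volume fractions |V1\V2|, |V2\V1|, |V1∩V2| of the union.

## Worked example

A phantom with one lesion whose contrast-enhancement focus is displaced
10 mm from the (coincident) PET foci — the classic "PET-positive,
non-enhancing" configuration:

```r
library(voxcord)
ctr <- 24 * c(2.036, 2.036, 2.027)
spec <- phantomSpec(
  lesions = list(lesionSpec(center = ctr, radiiMm = 14,
                            centerByModality = list(ce = ctr + c(10, 0, 0)))),
  rhoTarget = 0.8, seed = 11)
ph <- generatePhantom(spec)
cfg <- runConfig(ph$volumes$pet_tspo, ph$volumes$pet_aa,
                 ph$volumes$t1_native, ph$volumes$t1_ce, ph$volumes$t2,
                 petBackground = ph$truth@petBackground,
                 mriBackground = ph$truth@mriBackground)
res <- runPipeline(cfg)
res@correlations$TBR_GE180_vs_TBR_FET
res@overlaps$TBR_GE180_vs_rCE
res@quadrants$TBR_GE180_vs_rCE
```

prints

```
ConcordanceReport: TBR_GE180 (ordinate) vs TBR_FET (abscissa)
  r = 0.9578 (strong, ***), slope = 0.9666, intercept = 0.0532, n = 1118
  note: p-value treats voxels as independent observations; spatial autocorrelation is ignored
OverlapReport: TBR_GE180 vs rCE
  Dice = 0.0161, AHD = 7.202 mm (directed 7.202 / 5.913)
  fractions of union: V1-only 0.496, V2-only 0.496, intersection 0.008
QuadrantSummary: TBR_GE180 vs rCE over 1118 voxels
bothPositive    firstOnly   secondOnly bothNegative
      0.1547       0.2290       0.4705       0.1458
```

Reading: the two PET tracers are strongly concordant (r = 0.96, near-unit
slope), while the TSPO-PET hotspot barely overlaps the enhancement
hotspot (Dice 0.02) and sits ~7 mm away — the programmed 10 mm offset
minus the hotspot extent. 23% of analysis voxels are PET-positive without
enhancement (`firstOnly`), the phantom analogue of specific uptake beyond
the leaky-BBB region. `writeReports(res, dir)` persists everything as
JSON + CSV + NIfTI; `inst/scripts/voxcord.R` wraps phantom generation and
full runs for shell use.

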