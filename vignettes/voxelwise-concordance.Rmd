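---
title: "Voxel-wise PET/MRI concordance: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise PET/MRI concordance: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxcord)
```

## Scope and assumptions

`voxcord` quantifies, voxel by voxel, how much two imaging modalities
agree about a brain tumor — in intensity (does high TSPO-PET uptake occur
where contrast enhancement is high?) and in space (do the hottest
sub-volumes coincide?). The pipeline assumes its inputs are already
**co-registered on one grid**: registration and resampling are a
precondition, and the package refuses mismatched grids (shape, or spacing
beyond a 10⁻³ relative tolerance) rather than resampling silently, since
silent interpolation would blur exactly the voxel-scale heterogeneity the
analysis is after. Dynamic-PET kinetics, pharmacokinetic contrast
modelling and DICOM ingestion are out of scope.

## Normalization

PET volumes are converted to tumor-to-background ratios by dividing by
the mean uptake in a healthy contralesional background VOI (clinically a
crescent of grey and white matter). The mean is arithmetic and
unweighted. For MRI, relative contrast enhancement is the double ratio

$$\mathrm{rCE}(v) \;=\; \frac{\mathrm{CE}(v)/\mathrm{BG}_{CE}}
                            {\mathrm{T1}(v)/\mathrm{BG}_{T1}},$$

assumed proportional to contrast-agent concentration (valid for small
concentrations; no saturation correction is applied). Both normalizations
are invariant under global positive gains of the raw images, because the
gains cancel through the background scalars — a property the test suite
checks exactly.

Voxels whose native-T1 denominator is at or below a **validity floor** of
$10^{-6}\,\mathrm{BG}_{T1}$ (air, CSF after masking errors) are flagged
invalid, set to zero, counted, and excluded from every downstream
statistic; they never become infinities and behave as sub-threshold in
segmentation. The floor factor is deliberately tiny: it exists to catch
true numerical degeneracy, not to denoise.

## Segmentation and the analysis volume

Abnormal volumes are delineated by seeded iso-contour region growing: the
union, over seed points, of the connected component of
$\{v : I(v) \ge t\}$ inside a confining mask containing each seed. Design
choices where the convention was open:

* the threshold comparison is **inclusive** (≥);
* default connectivity is **face (6-neighbour)**, configurable to full
  (26-neighbour) — the common region-growing convention;
* default thresholds are 1.6 (TBR_FET, the biopsy-validated biological
  tumor volume), 1.8 (TBR_GE180, reflecting the TSPO tracer's lower
  healthy-background signal) and 1.3 (rCE and TBR_T2, visually defined
  hyperintensity); all overridable per run;
* one **shared confining mask** per dataset is used for all modalities.
  The confining mask is manual by nature (a generous margin excluding
  vessels and ventricles); phantom runs default to the whole grid minus
  the background VOIs;
* `autoSeeds()` replaces interactive seed clicks in unattended runs with
  every supra-threshold strict local maximum, in deterministic
  column-major order. A strict maximum is required, so intensity plateaus
  yield no automatic seed — supply explicit seeds for such images.

The analysis volume for correlations is the union of all modality
segmentations. T2 hyperintensity contributes voxels to this union but
joins no correlation or hotspot, since it serves only to include all
suspicious tissue.

## Hotspots

The hotspot of a segmentation is the connected set of its N hottest
voxels, grown greedily from the maximal voxel: at each step the
highest-valued region voxel adjacent to the current mask is added. N
derives from an equivalent-sphere diameter,
$N = \mathrm{round}\!\big((\pi/6)\,d^3/(s_x s_y s_z)\big)$, minimum 1;
the default $d = 10$ mm gives $N = 62$ at 2.036 × 2.036 × 2.027 mm
voxels. Rounding is to nearest (62.3 → 62); flooring would coincide here
but nearest-rounding is fixed so other spacings behave predictably.

Ties — two candidates of equal intensity at seed selection or on the
frontier — are broken by **lexicographic (column-major) voxel index**, a
rule chosen purely for reproducibility. If the hottest voxels form
disjoint islands, the greedy growth stays within the seed's island and
stops (with a warning) when the island is exhausted: the result is always
one connected region, by construction. The growth log is stored in the
`HotspotVolume`, so the frontier-dominance property (each added voxel
outranks every frontier voxel at its step) can be replayed and audited;
the test suite does exactly that.

## Concordance statistics

Pearson r and the OLS slope/intercept are computed over the analysis
volume, excluding rCE-invalid voxels. The regression ordinate is
TBR_GE180 against rCE, TBR_FET against rCE, and TBR_GE180 against
TBR_FET, and every report records its axis assignment. Strength classes
use the cut points 0.3 / 0.5 / 0.7 on |r|; the conventional open
intervals leave the boundaries unassigned, and this implementation
assigns boundary values to the **lower** class. Significance stars are
the usual 0.05 / 0.01 / 0.001 levels. Every report carries the caveat
that p-values treat voxels as independent although neighbouring voxels
are strongly correlated (reconstruction filters, biology): with 10²–10⁵
voxels per volume, stars are nearly always maximal and should be read as
decoration on r, not as calibrated inference.

Spatial agreement uses voxel-centre point sets: the Dice coefficient
$D = 2|V_1 \cap V_2|/(|V_1|+|V_2|)$, sub-volume fractions of the union,
and the symmetric average Hausdorff distance
$\mathrm{AHD} = \max\{d_\mathrm{AHD}(V_1,V_2),\,d_\mathrm{AHD}(V_2,V_1)\}$
with $d_\mathrm{AHD}(V_1,V_2) = \frac{1}{|V_1|}\sum_{a \in V_1}
\min_{b \in V_2} \lVert a-b \rVert$ in mm. Sub-voxel surface geometry is
not modelled. Distances are accumulated from direct coordinate
differences rather than the $|a|^2+|b|^2-2ab$ expansion, which loses
~8 digits to cancellation on coordinates far from the origin.

Because hotspots have equal size N by construction, every hotspot pair
satisfies two structural identities — equal exclusive fractions, and
$D = 2u/(1+u)$ with $u$ the intersection fraction of the union — which
the suite asserts on every pipeline run.

## The phantom: what it emulates, and what it does not

`generatePhantom()` emits five co-registered volumes (two PET tracers,
pre/post-contrast T1, T2) with known ground truth. Its purpose is to
realise exactly the statistical structure the pipeline assumes, with
every generative parameter recoverable downstream:

* **Geometry.** Default 48³ voxels at the scanner-like near-isotropic
  spacing 2.036 × 2.036 × 2.027 mm; voxel centres at
  $(i-1)\cdot s$. Lesions must fit with a 2-voxel margin.
* **Lesions.** Ellipsoids with per-modality centres (programming known
  inter-modality hotspot offsets) and per-modality amplitudes. The
  default profile is gaussian with $\sigma = r/2$ — smooth monotone
  fall-off guaranteeing a unique, connected hottest-N region. A flat
  profile (constant inside the ellipsoid) exists for correlation
  experiments, where a deterministic intensity gradient shared by both
  PET fields would add common variance and bias the recovered r upward;
  with a flat interior the voxel-wise correlation is governed purely by
  the programmed texture fields.
* **Correlated texture.** Inside lesions the two PET fields are
  modulated by $F_1 = S$ and $F_2 = \rho S + \sqrt{1-\rho^2}\,E$ with
  S, E i.i.d. standard normal, so their expected voxel-wise correlation
  is ρ. The texture coefficient of variation defaults to 0.25 of the
  lesion amplitude.
* **Enhancement.** The post-contrast T1 is the native T1 times
  $(1 + e\,E(v))$ with $E \in [0,1]$ a lesion-localised field; with
  noise off this identity is exact, which the suite exploits. Each
  emitted modality then receives independent additive Gaussian noise
  (default 5% of background) — so the e = 0 ⇒ CE ≡ native identity holds
  in the noise-free limit, as independent noise necessarily breaks it.
* **Defaults as conditions.** PET background 1 and amplitude 2 put the
  TBR peak near 3, comfortably astride the 1.6/1.8 thresholds; MRI
  background 100 with T2 amplitude 60 puts TBR_T2 near 1.6; enhancement
  factor 1 puts peak rCE near 2. No clinical cohort pins down
  quantitative noise or lesion-shape parameters for such phantoms, so
  these values were fixed once for testability, not cohort realism.
* **Not emulated:** PET count statistics (noise is homoscedastic
  Gaussian), partial-volume effects, attenuation, motion, registration
  error, anatomical texture. Passing phantom tests therefore validates
  the *computational* pipeline — normalization algebra, region growing,
  hotspot growth, metric formulas, parameter recovery — not robustness
  to scanner physics or registration imperfection on real data.

All intensities are clipped below at a small positive floor (10⁻⁶) so
ratio images are defined everywhere. Given an identical spec (including
seed), output is bit-identical; the RNG draw order (shared field,
correlated complement, then per-modality noise in a fixed modality
order) is part of the contract.

## Validation design and problem sizes

The suites run at desk scale, chosen so the full check completes in
about half a minute:

* metric formulas vs. all-pairs / set-arithmetic brute-force oracles on
  500 random mask pairs (grids ≤ 16³, ≤ 50 voxels; distances agree to
  10⁻⁹ mm);
* region growing vs. independent threshold-then-label flood fill on 200
  random structured 16³ images, both connectivities, exact agreement;
* greedy hotspot growth vs. an independent step-by-step simulation, plus
  the replayed frontier-dominance audit;
* correlation recovery at ρ ∈ {0, 0.3, 0.5, 0.8, 0.95}, ten phantoms
  each with > 5,000 flat-interior lesion voxels, requiring |r − ρ| ≤
  0.05 in at least 9/10. At the default 5% noise the attenuation of r is
  a factor ≈ 0.99 — inside the band even at ρ = 0.95;
* hotspot geometry recovery at programmed peak offsets 0/5/12/25 mm on
  noise-free phantoms. Here the hotspot diameter is set to 4 mm (N = 4):
  the AHD between two *extended* congruent sets systematically
  underestimates their centre offset by roughly the set radius, so a
  62-voxel (10 mm) hotspot cannot track a 5 mm offset to ±3 mm for any
  correct implementation; a hotspot small against the offsets makes the
  AHD an estimator of peak separation, which is the quantity under test.
  The 10 mm default is untouched everywhere else.

## Known limitations

Voxel p-values ignore spatial autocorrelation (flagged in every report).
The AHD implementation is O(|V1|·|V2|) — instant for hotspot-scale masks,
and still subsecond for segmentation-scale masks of a few thousand
voxels, but not intended for whole-brain masks. Hotspot extraction is
greedy, not a globally optimal maximal-sum connected subregion search;
plateau-valued images have no automatic seeds; and cohort-level
aggregation across datasets (means ± SD of per-patient metrics) is left
to the caller, who can bind the per-run CSV summaries.
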