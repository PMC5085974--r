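---
title: "Quantifying atelectasis change and its dosimetric impact: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying atelectasis change and its dosimetric impact: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atelect)
```

## The problem

Obstructive lobar atelectasis — collapse of lung tissue behind a blocked
airway — is common in centrally located non-small-cell lung cancer.  On CT a
collapsed lobe appears as a compact, high-density consolidated region.  When
the obstruction clears during radiotherapy (typically because the tumor
regresses), the lobe re-aerates: its volume increases, its density drops,
and nearby anatomy shifts by centimetres.  Such changes are far larger than
setup margins can absorb, so they matter both for understanding the tissue
itself (is re-aeration just air returning, or does edema drain too?) and for
the delivered dose to organs at risk when the original plan is carried
forward unchanged.

`atelect` implements the full measurement chain for baseline/midtreatment CT
pairs, and a synthetic thorax phantom generator with analytic ground truth
so that every stage can be validated end to end.

## Density calibration

Raw CT numbers drift with scanner state.  Each image is calibrated
independently with a two-point linear map fixed by two internal references:
the mean raw intensity of air outside the body is sent to 0 mg/cc and that
of blood in the descending aorta to 1050 mg/cc,

$$d(v) = 1050\,\frac{v - \mu_\text{air}}{\mu_\text{blood} - \mu_\text{air}}.$$

Calibrated voxels are *relative physical density* in mg/cc.  Because the map
is refit per image from its own ROIs, it is exactly invariant to any affine
drift in scanner output (`calibrate(a*raw + b)` with refit anchors equals
`calibrate(raw)`), which is the point of the procedure.  Values below air
(negative densities from noise) are deliberately *not* clamped: clamping
would bias ROI means and mass sums upward.

## Analysis masks

Lobe contours are more reliable than a direct atelectasis contour, but they
can include extra-pleural tissue at the outer lung surface.  The pipeline
therefore

1. removes the gross tumor volume from every lobe (tumor regression is a
   separate process and not part of lung mass change), then
2. erodes the *combined* lung — the union of the five lobes — twice with a
   3×3×3 structuring element, and intersects each lobe with the eroded
   combined lung.

Step 2 erodes each lobe from the lung exterior only: voxels on an interlobar
fissure are interior to the combined lung and survive, while the outer
pleural shell is removed.  "One voxel in all dimensions" is read as the full
26-neighbourhood (box) element; a 6-connected cross is available via
`element = "cross"`.  Outside the image counts as background.

Whether tumor removal happens before or after erosion is genuinely open; the
default removes the tumor first (so the erosion also retreats from the
tumor cavity), the opposite order is a one-line change, and a test documents
when the two differ.

## Mass, density, volume, and change

For a calibrated image and a binary ROI with voxel volume $v$ (ml):

* relative mass $= \sum_i d_i\, v$ (mg),
* relative density $= \overline{d_i}$ (mg/cc),
* volume $=$ voxel count $\times v$ (ml),

so mass $=$ density $\times$ volume holds exactly.  Changes are percent of
baseline, $100\,(x_\text{fu} - x_\text{bl})/x_\text{bl}$, computed per lobe.
Lobes are grouped as *atelectatic* (overlapping the atelectasis contour),
*healthy ipsilateral* (tumor side) or *contralateral*.  For sessions with
repeat scans, baseline and followup scans are paired by matched scan index
(`enumerate_pairings`), and the intra-patient SD across pairings is
available via `intra_patient_sd`.

## Resolution classification

Classification uses the atelectasis volumes only.  With baseline volume
$V_b$, followup $V_f$, $\Delta = V_b - V_f$ and $f = \Delta / V_b$:

* **none** if $f < 0.20$ *or* $\Delta < 15$ ml (volume increases included),
* **full** if $f > 0.80$ (and not floored),
* **partial** otherwise.

Boundary conventions are frozen as: $f = 0.80$ exactly → partial; $f = 0.20$
exactly → partial; $\Delta = 15$ ml exactly → not floored.  When the 15 ml
floor conflicts with $f > 0.80$ (a tiny baseline volume) the floor wins and
the label is **none**: the floor exists because delineation noise dominates
small volumes, and that argument applies regardless of the fraction.  All
thresholds are configurable (`resolution_config`).

## Rigid plan transfer

Two deterministic stand-ins for clinical daily-setup alignment:

* **Bone**: closed-form least-squares rigid fit (Kabsch / orthogonal
  Procrustes) of corresponding bony landmarks, restricted to a box region
  covering sternum and spine.  Exact for noiseless rigid motion; the RMS
  residual is reported.
* **Carina**: translation matching the carina mask centroids — rotation is
  identity by construction, mimicking carina-based volumetric image
  guidance.

Followup images and masks are pulled onto the baseline grid through the
transform (trilinear for scalars, nearest-neighbour for masks; out-of-field
scalars are filled with 0 mg/cc, i.e. air-equivalent density).

## The toy dose engine

Dose is recomputed with a deliberately simple radiological-depth model
(`compute_toy_dose`): for every voxel inside a beam's divergent aperture,

$$D = \sum_\text{beams} w\,\mathrm{MU}\,
  \exp\!\left(-\mu_\text{eff}\, \textstyle\int \rho/1000 \; \mathrm{d}\ell\right),$$

with the water-equivalent path length integrated from a virtual source at
1000 mm (midpoint quadrature along the ray) and
$\mu_\text{eff} = 0.005\,\mathrm{mm}^{-1}$ by default.  This is **not** a
clinical dose algorithm — no scatter, spectrum, or inverse-square term — but
it responds to density change along the beam path in the physically right
direction, which is all the pipeline needs to compare anatomies.  It is
deterministic, linear in beam weight, and additive over beams; tests pin all
three properties plus the closed-form exponential falloff in uniform water.

## DVH constraints

`dvh_metric` computes $D_\max$, $D_\text{mean}$, $D_\min$ (Gy) and $V_x$
(% of structure volume with dose $\ge x$; the lower bound is closed, and
boundary equality counts).  $V_{Rx}$ is $V_x$ at the prescription dose.
Default limits (`default_constraints`): spinal cord $D_\max$ 50.5 Gy,
esophagus $D_\text{mean}$ 34 Gy, heart $V_{40}$ 50% and $V_{60}$ 30%, and for
each of three lung definitions — all lung tissue (including atelectasis),
lung minus GTV, lung minus CTV — $D_\text{mean}$ 20 Gy, $V_{20}$ 30%,
$V_{30}$ 20%.  A constraint is *met* at `value <= limit` (limits are stated
as maxima, so exact equality passes).  A followup metric is *improved* if
its limit was unmet at baseline and met at followup, *worsened* for the
converse.  `metric_changes` summarises baseline→followup deltas per metric
and alignment (mean/SD/min/max), counts changes exceeding 1/2/5/10
Gy-or-percent, and counts patients with at least one change ≥ 5 Gy/5%.
The GTV is delineated per time point; the CTV is rigidly transferred.

## Cohort statistics

Group comparisons are two-sided and unpaired at $\alpha = 0.05$:

* `wilcoxon_rank_sum` — exact permutation distribution when the smaller
  group has ≤ 10 observations and the pooled data are tie-free (the
  resolution classes have 4–9 members, so exactness matters); otherwise the
  normal approximation with tie and continuity correction.
* `variance_f_test` — $F = s_x^2/s_y^2$ against $F_{n_x-1,\,n_y-1}$.

No multiple-testing correction is applied, matching the single-comparison
style of the analysis the package reproduces; treat the p-values
accordingly.  Whether the variance comparison pools full+partial against
none per metric or across metrics is left to the caller — both are a single
`variance_f_test` call on the corresponding subsets.

## The phantom generator

`generate_pair` builds both time points of an axis-aligned analytic thorax:
ellipsoidal lobes and heart, cylindrical aorta / esophagus / spine, a box
sternum and exterior-air reference box, a spherical tumor (29 ml by
default) and a concentric ellipsoidal atelectasis region inside one lobe.
Axis-aligned analytic shapes were chosen over anatomical realism because
every structure then has a closed-form volume, so the ground-truth record
never depends on voxel sums.  Raw intensities are an affine map of density
plus Gaussian noise (default 20 mg/cc equivalent, the scale of visible
parenchyma noise on CT, applied in raw units).  The whole followup anatomy
is displaced by a known rigid setup offset (default a 4/−3/2 mm
translation, so both alignment schemes should agree); landmarks move with
it.

### Effect model

With lobe volume $V$, atelectasis fraction $f$, resolution fraction $r$,
parenchyma density $\rho_p$ (250 mg/cc), consolidated density $\rho_c$
(1000 mg/cc), edema factor $u = 1/(1+e)$ and followup density scale $s$:

* baseline: fraction $f$ of the lobe is consolidated at $\rho_c$;
* followup: a fraction $r$ of the consolidated tissue re-aerates; its
  non-edema mass $r u \rho_c f V$ re-expands to $\rho_p$, so the lobe volume
  becomes $V' = V\,(1 + fr(\rho_c u/\rho_p - 1))$ and the lobe boundary is
  displaced outward (the growth factor is distributed anisotropically over
  the axes so the expanding lobe respects its neighbours);
* the remaining $(1-r) f V$ stays consolidated; all followup densities in
  the lobe are scaled by $s$.

With $e = 0$ and $s = 1$ re-aeration conserves mass exactly — the default
pair is exactly this "pure re-aeration" case, with density falling ~64% and
volume rising ~180%.  Healthy lobes keep their geometry and get a per-lobe
followup density scale drawn from N(0.96, 0.05) — a small mean decrease
with scan-to-scan variability, standing in for breathing-state differences.

For cohorts, per-class *targets* for percent density change $d$ and mass
change $m$ are drawn around class means, and the generator inverts the
model: with $Q = (1+m)/(1+d)$ equal to the volume ratio $V'/V$,

$$u = \frac{\rho_p}{\rho_c}\left(\frac{Q-1}{rf} + 1\right), \qquad
  s = (1+m)\,\Big/\,\frac{M'_{s=1}}{M},$$

both closed-form (`solve_effect_params`).  $u$ is allowed in $(0.02, 2.5]$ —
values above 1 mean the re-aerated tissue ends up less dense than
parenchyma, the mathematical price of decoupling the two targets — and
clamped draws record the realised, not the drawn, truth.  Default class
parameters: proportions 22/50/28% (full/partial/none), density means
−66.0/−25.6/−17.0%, mass means −2.8/−24.4/−9.2%, between-patient SDs 5 and
3 points, resolution fractions drawn uniformly from [0.85, 0.995],
[0.35, 0.65] and [0.17, 0.197], atelectasis fractions 0.70/0.45/0.50.  The
non-zero edema implied for the partial and none classes is what lets mass
fall faster than geometry alone would allow — consolidated tissue holding
fluid that drains on resolution.

### What the phantom does and does not emulate

It emulates: consolidation that re-aerates (volume up, density down), tumor
regression, stable healthy lobes with scan-to-scan density variability,
reference ROIs, bony landmarks with a rigid setup offset, and dose
gradients near the target.  It does **not** emulate respiratory motion,
sorting artifacts, beam hardening, realistic airway or fissure anatomy,
delineation error, or deformable anatomical change.  Green tests therefore
show the *computational chain* is correct and well-calibrated; they say
nothing about contouring quality or registration robustness on real scans.

Two scale caveats follow from the compact (~20 cm) thorax.  First, lobes
are 70–350 ml (adult lobes are larger) and the default tumor 29 ml.
Second, a two-voxel erosion is a much larger fraction of a 30 mm semi-axis
phantom lobe than of a real lobe at ~1.2 mm voxels — at the coarse cohort
grid it can remove half a small lobe, and a tumor-hollowed lobe may vanish
entirely (such lobes are dropped with a warning).  For this reason the
truth-comparison checks (mass conservation, parameter recovery) run the
pipeline with `eroded = FALSE`: phantom masks are exact by construction, so
the delineation-noise guard the erosion provides on real data would only
inject scale artefacts into the comparison.  `eroded = TRUE` remains the
default of `analyze_pair`, as it is the right choice on real contours.

### Tumor placement

The default tumor sits in the right upper lobe while the atelectasis
collapses the right lower lobe.  With near-whole-lobe collapse, a tumor
*disjoint* from the atelectasis inside the same lobe is geometrically
impossible under concentric analytic shapes, and overlapping them would put
ellipsoid–sphere intersection terms into every truth record.  Keeping them
in separate (ipsilateral) lobes keeps all truth closed-form; the anatomical
price — the obstructing tumor not sitting in the collapsed lobe's bronchus —
is irrelevant to anything the pipeline measures.

## Numerical choices

* Grids: default single-pair grid 64×64×56 at 3.2×3.2×3.8 mm; cohorts use
  48×48×40 at 4.2×4.2×5.0 mm.  These sizes keep a 50-patient cohort within
  seconds-to-minutes while voxelisation errors on percent changes stay well
  below the between-patient spread.
* Validation problem sizes: oracle cross-checks run 200 random instances
  with edges of 4–14 voxels; mass conservation uses 20 pure re-aeration
  phantoms; parameter recovery 20 replicates of 50-phantom cohorts (means
  pooled across replicates); test calibration 10,000 null replicates at
  group sizes (9, 41) and (4, 70).
* Ray quadrature: 64 midpoint samples per ray by default; the uniform-slab
  test uses more to isolate the quadrature error from the physics.
* Degenerate inputs fail loudly: empty ROIs, empty reference masks,
  non-congruent grids, inverted anchors, collinear landmarks, zero
  denominator variance.  Single-member groups report SD 0 with an explicit
  degeneracy flag rather than NA.
* Ties in the rank-sum test force the corrected normal approximation; all
  pooled values identical returns p = 1 with a degeneracy flag.

## Known limitations

The dose engine is for relative comparisons only.  Direction cosines are
assumed identity (no oblique scans).  Truth-level decoupling of density and
mass targets can imply physically odd edema factors for extreme draws.
Atelectasis and tumor cannot share a lobe.  Dose accumulation over
fractions, deformable registration, and biological dose models are out of
scope.
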