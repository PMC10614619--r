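---
title: "Quantifying membrane tubulation, tubule radii and curvature sorting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane tubulation, tubule radii and curvature sorting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memtube)
```

# Scope

`memtube` quantifies in-vitro membrane-remodeling experiments imaged by
confocal fluorescence microscopy: fields of liposomes that a curvature-active
protein deforms into tubules, nanometric tubules pulled from giant
unilamellar vesicles (GUVs), protein scaffolds that constrict preformed
tubules, and FRAP measurements of the mobility of lipids versus bound
protein. None of these measurements is a plain intensity readout; each rests
on a small amount of physics that this vignette spells out, together with
the package's tunable parameters and the design choices that were genuinely
open.

# The measurement models

## Sub-resolution tubule radius from integrated fluorescence

A membrane tubule of outer radius $r$ far below the diffraction limit
appears as a blurred line whose *apparent width is set by the PSF, not by
$r$*. What does encode $r$ is the total fluorescence per unit length,
$F_\ell$: the bilayer area per unit tubule length is the circumference
$2\pi r$, so with a membrane dye of areal fluorescence density $\rho_0$
(units per nm$^2$ of bilayer),

$$ F_\ell = 2\pi r \rho_0 \qquad\Longleftrightarrow\qquad
   r = \frac{F_\ell}{2\pi\rho_0}. $$

$\rho_0$ is calibrated from a flat lipid film on the coverslip
(`estimate_rho0()`): mean film intensity minus background, divided by the
pixel footprint in nm$^2$. The film is counted as **one** bilayer — this is
the convention that makes the calibration dimensionally consistent with a
single-bilayer tubule wall; a doubled (folded) film would halve every
estimated radius, which is why the calibration ROI must sit on a uniform
single-bilayer region.

$F_\ell$ is measured by `extract_profile()`: the image is sampled along a
supplied centerline, at each position the intensity is integrated across
the perpendicular cross-section (bilinear interpolation, 0.5-px steps), and
a per-profile background density — the median of flanking bands just
outside the integration width — is subtracted. Because Gaussian blur
preserves integrals, this estimate is independent of the PSF width as long
as the integration width covers the whole blurred cross-section; 6 PSF
sigmas or more is recommended (default width 2000 nm at a 120 nm PSF
sigma). The estimator is exactly linear in $F_\ell$ and inversely linear in
$\rho_0$.

## Curvature sorting ratio

Protein enrichment on the highly curved tubule relative to the flat-ish GUV
surface is quantified as

$$ S = \frac{(F_\mathrm{protein}/F_\mathrm{lipid})_\mathrm{tubule}}
            {(F_\mathrm{protein}/F_\mathrm{lipid})_\mathrm{GUV}}, $$

each $F$ an integrated, background-corrected profile fluorescence
(`sorting_ratio()`). Normalizing the protein signal by the lipid signal in
the *same* region cancels the membrane geometry (how much bilayer the PSF
integrates over), so $S$ is a pure surface-density ratio. $S$ is exactly
invariant to any global gain applied to either channel and to background
offsets removed by the flanking-band correction. No polarization correction
is applied: dye orientation effects on the curved versus flat membrane are
deliberately not modeled, so a few percent of systematic error on real data
is possible; the synthetic generator does not emulate polarization either,
which is one reason a green test here does not certify real-data accuracy
(see *What the generator does not emulate*).

The GUV reference is read from an equatorial-arc profile on the side of the
GUV away from the tubule attachment point, where the rim is unperturbed.

## Tubulation efficiency

For liposome fields, `predict_labels()` segments each image into
background/tubule/vesicle with a trainable pixel classifier: a multi-scale
feature bank (Gaussian smoothings, gradient magnitude, Laplacian, Hessian
eigenvalues and ridge measure at configurable scales, default
$\sigma \in \{1,2,4\}$ px) feeding a seeded random forest — the same family
of model the Trainable Weka Segmentation plugin defaults to. Because a pixel
classifier has no notion of object shape, round objects are occasionally
labelled "tubule"; `reassign_by_shape()` applies the corrective rule: any
tubule-classified component failing **any** of elongation ≥ 3, area ≥ 50 px,
mean width ≤ 1000 nm is reassigned to vesicle. The rule is one-directional
(vesicles are never promoted) and idempotent. The thresholds are this
package's documented defaults — the original workflow's exact values are
unpublished — and are configurable via `shape_criteria()`.

The per-image statistic is
$\mathrm{ratio} = A_\mathrm{tubule}/(A_\mathrm{tubule}+A_\mathrm{vesicle})$,
computed after reassignment. Images are the unit of replication: ratios are
averaged per condition (`summarize_group()`, mean ± sample SD), and
conditions are compared with a two-sided Welch t test (two groups) or
ordinary one-way ANOVA (more), via `compare_groups()`. Welch rather than
Student is the default because image-level variances differ between
conditions with different tubulation levels; `var_equal = TRUE` switches to
the pooled test. Images in which no membrane objects are detected at all
yield an *undefined* ratio and are excluded from aggregation rather than
counted as zero — counting them as 0 would bias low-efficiency conditions
downward for a reason (an empty field of view) unrelated to tubulation.

## Scaffold-covered segments

`analyze_scaffold_tubule()` thresholds the protein profile at
`covered_threshold` (default 2) times its median to split a tubule into
covered/uncovered runs, merges runs shorter than `min_run_nm` (default
500 nm, about 4 PSF sigmas — shorter runs cannot be resolved reliably), and
converts each run's mean lipid $F_\ell$ into a diameter. Samples within
`guard_nm` (default 500 nm) of a run boundary are excluded from the mean so
that PSF blur across the diameter step does not mix the two segments'
signals. Segments are reported individually and in order along the
centerline, so callers can aggregate per segment or per tubule as they
prefer (both conventions appear in the literature; this package reports the
per-segment table and leaves aggregation explicit).

A misuse guard rejects calls whose "lipid" channel varies more than
`max_lipid_step_factor` (default 3) fold along the tubule: a genuine lipid
channel steps only by the diameter ratio between segments (≈1.4 for an
80 nm/55 nm constriction), whereas an accidentally swapped protein channel
steps by the enrichment fold (≈7). The guard would false-positive on a
legitimate >3-fold constriction; raise the factor in that regime.

## FRAP

`normalize_trace()` implements single normalization:
$(I(t)-\mathrm{bg}) / (\bar I_\mathrm{pre}-\mathrm{bg})$, so the prebleach
plateau averages exactly 1. No acquisition-photobleaching reference ROI is
modeled (none is available in the emulated protocol), and double
normalization is therefore not used. `recovery_metrics()` fits the
post-bleach samples with a single exponential
$I(t) = I_0 + A(1-e^{-t/\tau})$ — the minimal model able to express the
fluid-lipid-recovers / bound-protein-does-not contrast — by profiling
$\tau$ on a log grid (the two linear parameters are solved exactly at each
$\tau$) followed by golden-section polish, which cannot diverge the way an
unconstrained Gauss-Newton fit can. The mobile fraction is $A/(1-I_0)$,
clipped to $[0,1]$ with a flag; the half-time is $\tau\ln 2$. A trace whose
first post-bleach sample is above 95 % of the prebleach level is rejected
as "no bleach" rather than fitted. Recovery is deliberately *not*
interpreted through a diffusion model (no spot-radius D estimation): with a
single ROI and no bleach-profile information, $\tau$ is an empirical rate
only.

# The synthetic-scene generator

Every estimator is validated against `synthgen`'s planted ground truth. The
forward model deposits fluorescence per object using the same membrane
accounting the calibration inverts — flat film $\rho\,\mathrm{px}^2$ per
pixel, tubule $\rho\pi d$ per nm of centerline (splatted bilinearly at
pixel/4 steps), vesicles as projected disks, GUV rims as thin-shell rings —
then blurs with an isotropic Gaussian PSF and adds Poisson shot noise after
photon conversion, followed by Gaussian read noise and a uniform background.

Defaults (the generator's stated world; none of these is tuned after the
fact):

| parameter | default | why |
|---|---|---|
| pixel size | 100 nm | typical spinning-disk confocal sampling |
| PSF sigma | 120 nm | ~280 nm FWHM, a 1.2–1.4 NA objective at 560–640 nm |
| photons per unit | 0.02 | puts ~1000 photons on a flat-film pixel: realistic shot noise |
| read noise SD | 20 units | a few percent of typical signals |
| background | 50 units | non-zero to exercise background correction |
| lipid density | 5 units/nm² | arbitrary scale; all estimators are gain-invariant |
| tubulation-scene tubules | 400 nm wide, 3–10 µm long, curved | resolvable ribbons as in liposome-field images |
| vesicles | 0.4–1.5 µm radius disks | liposome size range |
| covered-flag threshold | enrichment > 2 | fixed, documented convention for the truth record |

`make_tubulation_scene()` places non-overlapping objects greedily until the
planted tubule-area fraction (counted from the truth label map itself) is
within 0.02 of target — internally it aims at 0.01 so seeds sit comfortably
inside the contract — and raises an explicit error when the packing is
infeasible. `make_guv_tubule_scene()` and `make_scaffold_scene()` pass
planted enrichments and diameters straight into the truth record, and also
record the measurement polylines so tests exercise the measurement path,
not a tracing algorithm (automatic tracing is out of scope). All scenes are
single 2D planes with 0-based pixel-centred coordinates; the same seed
reproduces a scene bit-for-bit.

**What the generator does not emulate**, hence what a green test does *not*
establish about real data: polarization of dye emission on curved
membranes; depth-dependent PSF asymmetry and z-sectioning of a 3D GUV
(the rim is rendered as an idealized 2D ring); camera fixed-pattern noise
and saturation; membrane fluctuations, tubule Brownian motion and focus
drift during acquisition; chromatic misregistration between channels; and
the possibility that a real flat film is not a single bilayer. Estimator
accuracy on synthetic scenes bounds algorithmic error only.

# Numerical choices and degenerate inputs

* Convolution uses edge-inclusive reflection padding; feature stacks are
  exactly equivariant under 90° rotations and mirrorings (tested).
* Components are 8-connected; component class is the majority pixel class;
  components below `min_object_area_px` (10 px) are dropped as speckles.
* Axis lengths use the image-moments ellipse convention
  (axis $=4\sqrt{\lambda}$ of the pixel covariance, with the 1/12
  pixel-footprint term), so a disk has elongation ≈ 1; skeletons come from
  Zhang–Suen thinning and skeleton length counts orthogonal steps as 1 and
  diagonal steps as $\sqrt 2$.
* `estimate_radius(0, ...)` returns radius 0 flagged degenerate instead of
  erroring; negative $F_\ell$ errors. `estimate_rho0()` errors when the
  background-subtracted film density is non-positive.
* TIFF I/O never rescales intensities — the calibration algebra depends on
  raw units — and a missing pixel size is an error, never a silent default.
* The random forest (50 trees, depth ≤ 12, mtry = √p) and all sampling use
  R's RNG under the caller's seed, so training is reproducible; prediction
  is a pure function of the model.

# Known limitations

* The pixel classifier is trained per imaging configuration; applying a
  model to images with a very different pixel size or noise level degrades
  accuracy silently (a feature-count mismatch errors, a distribution shift
  does not).
* Centerlines are supplied by the caller (or taken from skeletons); there
  is no automatic tubule tracing.
* The shape-criteria defaults substitute for the original workflow's
  unpublished values; absolute tubulation ratios are comparable within a
  configuration, not across differently tuned pipelines.
* Sorting ratios assume both dyes report membrane area linearly;
  self-quenching or polarization effects at high curvature are not
  corrected.
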