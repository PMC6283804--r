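---
title: "Hybrid planar/SPECT dosimetry: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid planar/SPECT dosimetry: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redosim)
```

This vignette is the package's account of the science it implements: the
dose-calculation model and its assumptions, the synthetic data generator and
what it does (and does not) emulate, the numerical choices, and the design
decisions taken where the method leaves room.

## The dosimetry model

Internal dosimetry after Re-188 Lipiodol radioembolization needs, for every
source region (tumor, entire liver, lungs, stomach, spleen, kidneys), the
*time-integrated activity* — the total number of decays occurring in the
region — and an S-factor converting decays into absorbed dose. The imaging
protocol provides two complementary measurements:

* **2–3 whole-body planar scans** (anterior + posterior) at roughly 3, 24
  and 48 h post-injection. Without transmission imaging, no attenuation or
  scatter correction is possible, so planar count rates are only *relative*
  measures of activity — but their time dependence is reliable, because the
  (unknown) attenuation of a fixed ROI does not change between scans.
* **One quantitative SPECT/CT** at the first time point, reconstructed with
  attenuation, scatter, dead-time and resolution corrections and converted
  to MBq with a camera calibration factor. It yields one *absolute* activity
  per region, at one time.

The hybrid method combines them: fit the planar TAC shape, then rescale the
fitted curve so that it passes through the SPECT measurement.

### Conjugate-view quantification

The planar workflow mirrors standard conjugate-view processing. ROIs are
drawn on the first scan by thresholding at 40% of the maximum inside a
manually supplied rough boundary (the threshold comparison is inclusive;
ties are kept). Later scans are registered to the first and the ROIs
transferred. The region count rate is the geometric mean
$\sqrt{R_{ant} R_{post}}$, which for a source at depth $d$ in a uniform
attenuator of thickness $T$ equals $R_0 e^{-\mu T/2}$ *independently of*
$d$ — the property that makes planar quantification usable at all. The
implementation preserves this identity exactly: the projector attenuates
each voxel by the material in front of it plus half its own thickness, so
the product of anterior and posterior attenuation factors is the full-column
transmission for any source position.

Count-rate losses are modelled as paralyzable dead time,
$m = n e^{-n\tau}$, applied to the image-total rate. The correction inverts
this with the principal Lambert W branch, $n = -W_0(-m\tau)/\tau$, which is
exact on the physical branch $n \le 1/\tau$; observed rates above the
paralyzable maximum $1/(e\tau)$ are rejected, and corrections above 30%
(configurable) are flagged.

Registration is translation-only. Whole-body scans 45 hours apart are
misaligned mainly by couch/patient offsets along the bed axis; a rotation
search would add cost and failure modes for little benefit at the pixel
sizes involved. This is a documented limitation rather than an oversight.

### Kinetics

Each region's samples are fit by weighted least squares to
$$A_{rel}(r_S, t) = a\, e^{-\frac{\ln 2}{T_{eff}} t},$$
with weights $1/\sigma^2$ from Poisson error propagation of the ROI counts
($\sigma_{GM} = \tfrac12 GM \sqrt{1/N_{ant} + 1/N_{post}}$). The fit is
performed in *linear* space, where those weights have their literal
meaning; the log-linear closed form is used only as the initializer. With
two points the exact closed form is returned and $R^2 = 1$ by construction.
Non-decaying or constant data are errors, not silent extrapolations: a
non-positive or infinite half-life cannot be integrated downstream.

Effective and biological half-lives are related by rate addition,
$1/T_{eff} = 1/T_{phys} + 1/T_{bio}$ with $T_{phys} = 17$ h; $T_{eff} =
T_{phys}$ maps to $T_{bio} = \infty$ (no biological clearance), and
$T_{eff} > T_{phys}$ is rejected as unphysical for a closed system. Fitted
values above $T_{phys}$ on noisy data are reported with a warning rather
than clipped — the user decides.

With only three imaging points a bi-exponential cannot be constrained, so
fitting is deliberately mono-exponential everywhere. The *generator* can
nevertheless produce bi-exponential and two-phase ground truth (below),
precisely so that the consequences of this model mismatch can be studied.

### Rescaling, integration, dose

The absolute TAC anchors the fitted shape at the SPECT time:
$A(t) = a \frac{A(r_S,t_1)}{A_{rel}(r_S,t_1)} e^{-\ln 2\, t / T_{eff}}$.
The scale uses the *fitted* curve evaluated at $t_1$, not the raw first
sample: the raw sample carries noise that would propagate into every dose,
whereas the fitted value is the maximum-use estimate of the curve at that
time. The raw-sample variant is available (`rel_at_t1` argument) for
sensitivity analyses. Evaluated at $t_1$, the curve equals the SPECT
activity exactly.

The time-integrated activity uses three analytic segments:

* $0 \to t_1$: linear growth from 0 to $A(t_1)$ (the injection and
  distribution phase is not imaged; a linear rise is the standard neutral
  assumption, contributing $A(t_1) t_1 / 2$);
* $t_1 \to t_{last}$: the fitted exponential;
* $t_{last} \to \infty$: pure physical decay — after imaging ends, the
  conservative assumption is that the radiopharmaceutical stays in tissue.

For two-scan patients the tail attaches at the second scan, by the same
rule. For single-scan protocols there is no fitted segment; the assumed
half-life (physical, or a population effective value) applies from $t_1$
to infinity, including the linear rise before $t_1$. A consequence worth
knowing: under purely mono-exponential kinetics, the {3,24} subset acquires
a small systematic positive offset against the three-point reference,
because its physical tail starts 24 h earlier than the reference's — the
subset study results should always be read with the tail rule in mind.

Dividing by the injected activity gives the TIAC
$\tilde a(r_S) = \tilde A(r_S)/A_0$, bounded above by
$T_{phys}/\ln 2 = 24.5$ h (total retention of all injected activity).

Doses use S-factors. The published organ S-values for this therapy sit in
external software; the package's default is the **local beta-deposition
model** $S = \Delta_\beta / m$ (0.763 MeV mean beta energy per decay,
giving 4.40 mGy/(MBq·h) per 0.1 kg), which is the physically dominant term
for Re-188: its gamma cross-doses are negligible against the beta
self-dose. Any user-supplied reference table overrides the default and is
mass-scaled as $S(m) = S_{ref}\, m_{ref}/m$, the correct scaling for
non-penetrating emissions. Tumors are dosed with a sphere-model series
interpolated log-log in mass (exact for any power-law series), with tissue
density 1.03 g/mL. Tumors below 20 mL trigger a partial-volume warning:
at sizes near system resolution the SPECT activity (hence the dose) is
biased low by tens of percent, and for a 2.3 mL tumor the bias can exceed
40%.

## The synthetic cohort generator

The generator exists so that every stage — ROI thresholding, registration,
dead-time inversion, geometric means, fitting, segmentation, integration —
can be tested end-to-end against known ground truth.

**Anatomy** is a stylized ellipsoid phantom (40×24×56 voxels at 8 mm): a
body, a liver containing a tumor, lungs (with lower attenuation), stomach,
spleen and kidneys. All active regions except the tumor have disjoint
anterior–posterior projection footprints, so their planar TACs are
uncontaminated; the tumor unavoidably projects inside the liver, exactly
as in patients. This is why exact-recovery tests share one half-life
between tumor and liver, while statistical tests use distinct draws (their
population means differ by only 0.1 h, so the contamination bias at cohort
level is far below the test tolerances).

**Kinetics.** Per region, uptake fractions at $t_1$ and effective
half-lives are drawn per patient. Defaults encode the study conditions:
half-lives from truncated normals (liver 12.6 ± 1.7 h, tumor 12.5 ± 1.9 h,
lungs 12.0 ± 1.9 h, stomach 10.9 ± 1.9 h, spleen 14.7 ± 2.3 h, kidneys
12.8 ± 2.5 h; truncated to (2, 17] h), tumor uptake log-uniform over
1–30% of injected activity, injected activity log-uniform over 1296–7162
MBq, scan times {3, 24, 48} h with optional jitter (±1, ±1, ±4 h) and an
optional two-scan fraction. Organ uptake ranges (liver 25–55%, lungs 1–4%,
stomach 1–3%, spleen and kidneys 0.5–2%) are fixed, physiologically
plausible choices — large hepatic retention, small systemic redistribution
of free perrhenate. Two optional departures from mono-exponential truth
exist for the interval study: a bi-exponential mixture (a slow component at
a configurable half-life) and a two-phase model (effective decay up to a
break time, physical decay after), the latter matching the observed
pattern that the 24–48 h interval half-life approaches the physical value.

**Physics.** Planar images are attenuated line-integral projections
(mid-voxel convention, preserving the conjugate-view identity to machine
precision) scaled by a camera sensitivity (6 cps/MBq); counting applies a
global paralyzable loss (τ = 1 µs, keeping losses below 6% at the rates the
activity range produces) and per-pixel Poisson noise at an effective dwell
of 40 s (a 10 cm detector row at 15 cm/min bed speed). Later scans get
random integer couch shifts (±2 pixels). The SPECT volume is the voxelized
activity map, optionally blurred by an isotropic Gaussian (FWHM 12 mm
default — the resolution scale of Re-188 SPECT, emulating partial-volume
spill-out) with Poisson noise at 25 counts/MBq.

**What it does not emulate** — and therefore what passing tests do not
show about clinical data: no projection-domain SPECT simulation or
reconstruction artefacts, no scatter, no intra-region heterogeneity, no
organ motion or deformation between scans (registration is exercised with
rigid shifts only), no manual-delineation variability (rough boundaries
come from the true footprints), and a single shared anatomy across the
cohort. Tests on this generator validate the *computational chain*, not
the clinical accuracy of planar quantification.

## Numerical choices

* Volume-matched tumor segmentation is implemented as top-$k$ voxel
  selection rather than a threshold search: the "fixed threshold such that
  the recovered volume equals the reported volume" defines a constraint,
  and top-$k$ satisfies it deterministically and exactly to one voxel.
  Ties at the cut break by voxel index; the segmented *activity* is
  invariant to the tie-break.
* The 40% threshold is applied per view independently (the anterior and
  posterior maxima differ); thresholding the geometric-mean image instead
  is available via `threshold_on = "gm"`.
* Registration maximizes normalized cross-correlation over integer shifts
  in a ±8 pixel window; ties break toward the smaller shift. Flat images
  are an error (undefined correlation).
* The rank-sum test enumerates all assignments exactly (ties included) up
  to a combined sample size of 12, and uses the tie-corrected normal
  approximation with continuity correction beyond. Quartiles use linear
  interpolation between order statistics (R type 7), configurable.
* Cohort summary SDs use the sample convention ($n-1$); a single-entry
  region reports SD 0 with a message.
* Times are hours post-injection throughout; voxel indices are 0-based in
  world-coordinate formulas with coordinates at voxel centres.

## Problem sizes

The test suite and the acceptance script run synthetic cohorts of 10–20
patients (and 5 × 20 for the half-life recovery summary) on the 40×24×56
phantom — sizes at which the statistical checks are well-powered for the
tolerances tested while the whole suite stays interactive on a laptop.
Larger cohorts or finer grids are a matter of arguments, not code changes.

## Known limitations

* Planar cross-contamination between overlapping regions is inherent to
  the conjugate-view geometry; per-patient fitted half-lives for liver and
  tumor can deviate by 1–2 h when their true kinetics differ, although
  cohort means are nearly unbiased.
* The default S-factors neglect photon cross-dose entirely; absolute organ
  doses with the default table are therefore a local-deposition
  approximation, and users with access to published phantom S-values
  should supply them.
* No partial-volume correction is applied (matching the method being
  modelled); small-object activities are biased low by construction when
  blur is enabled.
* Healthy-liver (tumor-excluded) dose and bone-marrow dose are out of
  scope, as are voxel-level dose maps.
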