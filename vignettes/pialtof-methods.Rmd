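---
title: "Modelling flow-related enhancement in mesoscopic TOF angiography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling flow-related enhancement in mesoscopic TOF angiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pialtof)
```

## The problem

Pial arteries on the cortical surface are mesoscopic: 50–300 µm in
diameter, comparable to or smaller than the voxels of even aggressive
high-resolution time-of-flight (TOF) MR angiography protocols. TOF
contrast needs no exogenous agent — inflowing blood that has experienced
few RF pulses is simply brighter than the RF-saturated static tissue — but
whether a mesoscopic artery is visible depends on an interplay of blood
delivery time, sequence timing, and, dominantly, the ratio of vessel to
voxel size. `pialtof` implements the quantitative machinery needed to
reason about this regime: the signal equations, a cylinder-in-voxel
partial-volume model, a displacement-artefact model, protocol
optimization, a fully labelled synthetic phantom, the
threshold/region-growing segmentation pipeline, and two-echo T2\*-based
removal of pial veins.

## Signal model

Static tissue imaged with a spoiled gradient-echo (FLASH) sequence reaches
the steady state

$$M_z^{S} = M_0\,\frac{1-e^{-TR/T_1}}{1-e^{-TR/T_1}\cos\theta},$$

while blood that entered the slab fully relaxed and has experienced
$n$ RF pulses carries

$$M_z^{blood}(n) = M_z^{S,blood} +
\left(e^{-TR/T_{1,blood}}\cos\theta\right)^{n-1}\left(M_0 -
M_z^{S,blood}\right),$$

with $n = t_{delivery}/TR$ set by the blood delivery time. The
flow-related enhancement (FRE) is the relative contrast
$(M_z^{blood}-M_z^{S,tissue})/M_z^{S,tissue}$; the $\sin\theta$ excitation
factor cancels in the ratio. Defaults are 7 T values: $T_1$ of
blood/tissue 2100/1950 ms.

Numerical choices:

* **Pulse-count discretization.** The delivery time is converted to an
  integer pulse count as `max(1, round(delivery/TR))`; relaxation during
  the fractional remainder of a TR is not modelled, consistent with the
  plug-flow assumption (each voxel's blood is treated as a single
  coherent segment — dwell times at these voxel sizes are far below TR,
  so multiple velocity segments per voxel are unnecessary). The closed
  form is property-tested against a pulse-by-pulse recursion at 1e-10.
* **Angles** are degrees at every interface and radians internally.
* **Optimization** (`optimal_flip_deg`) is an exhaustive grid search at
  0.05° with ties broken toward the smaller angle and the result rounded
  to the nearest degree; with integer pulse counts it reproduces the
  protocol optima 37°/21°/16°/11° for delivery times of
  100/300/500/1000 ms at TR 20 ms, and the Ernst angle
  $\arccos(e^{-TR/T_1}) = 8.2°$ for tissue. Note the Ernst angle
  maximizes the *received* signal $M_z\sin\theta$; the longitudinal
  magnetization alone is monotone in flip angle.

## Partial-volume model

A vessel is modelled as a cylinder of diameter $d$ whose axis passes
through the centre of an isotropic voxel of edge $l$, parallel to an
edge. The blood volume fraction reduces to a circle–square overlap over
$l^2$, with three exact regimes: full ($l \le d/\sqrt2$), inscribed
circle ($l \ge d$, fraction $\pi d^2/4l^2$), and the circular-segment
formula in between. The two-compartment voxel magnetization
$V\,M_z^{blood} + (1-V)\,M_z^{S,tissue}$ gives a partial-volume FRE that
factorizes exactly as $V \cdot \mathrm{FRE}$, so voxel-size gains are
pure geometry: shrinking voxels from 0.8/0.5/0.4 mm to 0.3 mm around a
300 µm vessel predicts gains of 611%/178%/78%, independent of delivery
time. The intermediate-regime formula is verified against a Monte-Carlo
rejection oracle (1e7 points, 1e-3 relative), and the off-centre/oblique
cases are handled empirically by the phantom rasterizer rather than by
the closed form — a stated limitation of the centred model.

## Vessel displacement

Blood moving along a phase-encoding direction between the phase-encoding
blip and the echo is mispositioned by $\Delta y = -v_y(TE - t_{pe})$.
The sign convention follows the equation as written (positive velocity,
negative shift); the CLI reports magnitude and sign separately. At
pial-artery velocities (the package exposes the bounds as inputs rather
than hard-coding a range) a 5 ms delay displaces vessels by 25–250 µm —
of the order of a voxel, which is why the two echoes of a dual-echo scan
show visibly shifted vessel centrelines.

## The phantom: what it emulates and what it does not

`build_phantom()` is the package's ground-truth generator. It emulates
the features the downstream pipeline is sensitive to: sparse binary
branching trees with branch angles drawn near 90° (±15°, truncated),
child diameters tapering by 0.75, velocities assigned monotonically in
diameter within 10–50 mm/s, blood delivery times accumulating from
200 ms at the slab entry, artery T2\* close to tissue (30 vs 33 ms) and
vein T2\* markedly shorter (12 ms), Rician noise, and a smooth
multiplicative bias field. Rasterization uses supersampled
point-in-cylinder counting (factor 7, antialiased with a one-sub-cell
linear ramp; centred-cylinder fractions agree with the analytic model
within 0.02) and emits fraction, delivery-time, artery/vein label and
ground-truth mask volumes. The simulated signal decays compartment-wise:
$S = V M_z^{blood} e^{-TE/T_2^{*,kind}} +
(1-V) M_z^{S,tissue}e^{-TE/T_2^{*,tissue}}$ — a single "mixed" T2\* is
not well defined for a partially filled voxel, and the compartment form
reduces to the expected limits at $V \in \{0, 1\}$.

Deliberate defaults, chosen once:

* **Default tree depth 2** (diameters 0.60/0.45/0.34 mm at 0.3 mm
  voxels). This places the default world in the vessel ≈ voxel regime
  the method targets. With deeper trees (0.21 mm leaves) the noiseless
  mask-level Dice tops out near 0.73 — precisely the partial-volume
  contrast collapse the model predicts — so a Dice ≥ 0.8 expectation is
  only meaningful in the resolved regime. The generator covers 50–700 µm
  via configuration.
* **Default veins are "pass-through"** (short delivery, enhancing),
  mirroring the large through-going veins and sinuses that actually
  contaminate TOF angiograms; fully saturated veins (the
  `vein_pass_through = FALSE` world) are invisible to TOF segmentation
  by construction and only matter for testing that they do *not* appear.
* **Per-tree FOV slabs.** Each tree is confined to its own slab of the
  field of view so that distinct trees cannot merge into one connected
  component; per-component artery/vein classification would otherwise be
  ill-posed in the ground truth itself. Real cortical anatomy is *not*
  spatially sorted like this — it is a testability device.
* The phantom does not emulate: realistic cortical folding geometry,
  k-space/reconstruction effects (GRAPPA, zero-filling, slab profiles),
  motion, laminar flow profiles, or B1 inhomogeneity.

A green phantom test therefore establishes algorithmic correctness under
the stated geometry and noise model, not in-vivo performance.

## Segmentation

The pipeline mirrors a deliberately simple semi-automatic scheme: global
primary threshold, removal of clusters with *fewer than* 10 voxels
(5 for low-resolution data; the boundary cluster of exactly the minimum
size is retained), then iterative region growing that adds any connected
voxel above a lower secondary threshold — a fixed point with set
semantics, independent of seed order. Connectivity defaults to 26, the
most permissive choice for thin oblique vessels. Thresholds are explicit
configuration (in practice they are adjusted per slab); an optional
percentile-based auto-threshold exists but is off by default. For the
default phantom the stated thresholds are 1.7× / 1.5× the tissue signal:
the ground-truth mask cuts at half the attainable blood fraction, which
for the dimmest default vessels sits at an intensity near 1.5× tissue.

Bias-field correction is *not* re-implemented from the published tools;
a homomorphic stand-in divides by a Gaussian-smoothed copy of the image.
Two numerical details matter. First, plain renormalized smoothing is
biased at the volume faces (one-sided windows under a sloping field,
3–9% error); each smoothing pass is therefore a local-linear
(Savitzky–Golay) fit, which is first-order exact at edges, followed by a
global degree-2 log-polynomial residual correction. Second, a
multiplicative field is identifiable only up to scale, so "recovering" a
flat volume means flatness (≤ 2% deviation about the median), with the
global median preserved by convention. Denoising is an optional identity
hook — preprocessing, not contribution.

Skeletonization is topology-preserving sequential thinning
(simple-point removal, six directional sub-iterations, line-end
preservation); skeleton length is voxel count × voxel size. Both the 3D
and the projection (MIP) variants are exposed since reported lengths can
reasonably be computed either way; solid bars may lose up to one voxel
per end before the end-point criterion engages.

## Vein removal

Oxygenated arterial blood has T2\* close to tissue; deoxygenated venous
blood is markedly shorter. From a dual-echo acquisition
(TE 7.05/14 ms by default) the voxelwise estimate is
$T_2^* = \Delta TE / \ln(S_1/S_2)$, with degenerate voxels
($S_2 \ge S_1$, as happens under noise) clamped to 1000 ms and flagged.
A connected component is classified venous when the 90th percentile of
its unclamped T2\* values falls below the threshold — 19 ms normally,
27 ms when artefactually merged artery–vein components must be
protected (a documented failure mode: a merged component is judged by
its pooled percentile). Components with no valid estimate default to
arterial. The percentile convention (linear interpolation, `quantile`
type 7) is configurable because none is canonical.

One estimator subtlety: the two-point T2\* is *median*-unbiased (≤ 1.3%
at SNR 20 across 10–40 ms) but not mean-unbiased — the log-ratio
denominator makes the arithmetic mean diverge as $S_1 \to S_2$. This is
exactly why the component statistic is a percentile and why tests assess
the median.

For protocols where the second echo is only feasible at low resolution,
`mark_veins_from_lowres()` carries a low-resolution venous mask to the
high-resolution grid by nearest-neighbour resampling and flags
high-resolution components with ≥ 50% overlap.

## Known limitations

* The closed-form fraction assumes a centred, axis-aligned cylinder;
  off-centre vessels are only handled by the rasterizer.
* Diameter estimation is deliberately out of scope (relative errors are
  large when diameter ≈ voxel).
* NIfTI support is a minimal single-file NIfTI-1 reader/writer (uint8,
  int16/32, float32/64, gzip) — not a general neuroimaging I/O layer.
* The CLI accepts JSON configuration files only.
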