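---
title: "Quantifying NPC protein crowding with a ratiometric FRET probe: models and conventions"
author: "npcrowd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying NPC protein crowding with a ratiometric FRET probe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npcrowd)
```

# The measurement

GimRET is a FRET pair of CFP (donor) and a glycine-inserted YFP
(YFP1G, acceptor).  The acceptor's fluorescence decreases as the local
protein concentration rises, while CFP is insensitive to crowding, so
the acceptor/donor intensity ratio reads out macromolecular crowding:
the lower the ratio, the more crowded the probe's surroundings.  Fused
to a nucleoporin, the probe reports crowding around that Nup inside the
nuclear pore complex.

`npcrowd` treats this experiment as three measurement problems —
spectroscopy, interphase imaging, mitotic time lapse — backed by a
synthetic-data generator that knows its own ground truth.  This
vignette records the models, parameter choices and numerical
conventions, and what the synthetic validation does and does not show.

# Spectra and the quench calibration

## The probe signal

For an emission spectrum sampled on a uniform wavelength grid the probe
signal is

$$ A/D \;=\; \frac{\sum_{520 \le \lambda \le 570} I(\lambda)}
                  {\sum_{460 \le \lambda \le 500} I(\lambda)} $$

with both band endpoints inclusive.  The band statistic is deliberately
a **grid-point sum**, not a quadrature: it mirrors the "total
fluorescence in a window" read-out of a spectrometer.  Its absolute
value depends on the grid step, so only ratios of band sums taken on
the same grid are meaningful; the package never interprets absolute
band integrals.  `adRatio()` is exactly invariant (up to float
summation order, tested at 1e-14) under positive rescaling of the
intensities, which is why instrument gain and probe amount cancel.

A donor band sum at or below a configurable epsilon (default 1e-12)
raises an undefined-ratio error rather than returning Inf.

## Quench model

The acceptor quench factor is modeled as linear with a saturation
floor:

$$ f(C) = \max(1 - sC,\ \varphi), \qquad
   s = 1/500\ \mathrm{(mg/mL)^{-1}},\ \varphi = 0.2 . $$

The linear form is the simplest monotone model consistent with an
inverse concentration–fluorescence relationship and a usable dynamic
range beyond 200 mg/mL; the floor keeps the factor positive and encodes
saturation of the quench.  The donor is never scaled.  Calibration data
rarely constrain the floor (few experiments reach it), so
`fitCalibration()` holds the floor fixed and fits the two identifiable
parameters: the zero-concentration ratio $r_0$ (free, because absolute
A/D is instrument-dependent and never assumed to be 1) and the slope
$s$, by Levenberg–Marquardt least squares initialized from a linear
regression.  Data incompatible with a non-increasing calibration
(positive trend or residual RMS above 5% of $r_0$, configurable) set a
warning flag; the stored slope is clamped at zero so the fitted curve
always satisfies the monotonicity invariant.  Inversion is closed-form
on the linear segment and signals a saturation error carrying the
boundary concentration (0, or the floor onset $(1-\varphi)/s$) outside
the invertible range $(r_0\varphi,\ r_0]$.

## Synthetic spectra

The spectral phantom uses two donor Gaussians (475 and 501 nm, σ 15 nm)
and one acceptor Gaussian (527 nm, σ 12 nm, amplitude chosen so the
baseline A/D is ≈ 1.2), each truncated at a 510-nm crossover so that
each integration band sees a single component.  Real CFP/YFP spectra
overlap across 510 nm; the truncation is an idealization that makes the
generator's algebra exact — the A/D ratio of a phantom spectrum at
concentration $C$ over baseline equals $f(C)$ to 1e-9 — at the cost of
not exercising donor bleed-through.  That is intentional: the paper
convention this package follows defines the probe signal on raw band
counts with no spectral unmixing, so bleed-through would shift all
ratios by a common factor that cancels in every relative statistic the
pipeline reports.

# Interphase images

## Image formation model (generator)

A cell is a cytoplasmic disk (radius 110 px in a 256×256 frame), a
nucleus (radius drawn from 55–70 px, jittered center), and a
nuclear-envelope rim band of width 3 px just outside the nucleus
boundary.  Per pixel:

* donor = `background + photonScale · Dblur`
* acceptor = `background + photonScale · Dblur · baselineAD · f(C)`

where `Dblur` is the probe-density field convolved with a Gaussian PSF
(σ 1.5 px), `f` the quench factor, and `C` the **unblurred** crowder
concentration map — crowding is a chemical property of the local
environment, not an optical one, so the PSF is applied to the density
(photon) field only.  Optional shot noise is per-pixel Poisson,
independent per channel; Gaussian read noise is omitted (it is small
relative to shot noise at hundreds of counts and would only widen the
tolerances).

Default densities (rim 3, cytoplasm 1, nucleoplasm 0.15 relative
units; `photonScale` 200 counts per unit over a background of 100
counts) give a visibly bright rim over diffuse cytoplasm and a dim
nucleus, i.e. confocal-like contrast for an NPC-localized probe.
Concentrations are preset conventions chosen so that, routed through
`f`, they reproduce the characteristic crowding signatures of each NPC
region class:

| preset | C rim (mg/mL) | C cyto | expected `[probe]_NE/[probe]_Cyto` |
|---|---|---|---|
| `peripheral` | 200 | 100 | 0.60/0.80 = 0.75 |
| `central_cavity` | 140 | 100 | 0.72/0.80 = 0.90 |
| `scaffold` | 180 | 100 | 0.64/0.80 = 0.80 |

The manifest carries the exact masks, the concentration map, and
expected read-outs recomputed from the map at generation time.
Crucially, expected crowding is independent of the density fields, so
expression level and crowding are decoupled by construction — the
generator can therefore *test* whether the pipeline keeps them
decoupled, but cannot tell the pipeline the answer.

## Segmentation

`segmentCell()` operates on the donor channel only (the acceptor is
crowding-attenuated at the rim, which would bias a threshold).  Steps:
light Gaussian smoothing (σ 2 px), global Otsu threshold, largest
connected component, hole-filling; the nucleus is the largest enclosed
dim region.  Because PSF blur erodes the thresholded hole inward of the
true nuclear boundary, the rim band (width `rimWidth`, Euclidean
distance-transform band) is slid outward by an integer offset of 0–8 px
and anchored at the offset whose band has the highest mean donor
intensity — the nuclear-envelope ridge.  The cytoplasm mask is eroded
away from the outer cell edge, and the background estimate is the
median of background pixels at least 8 px from the cell, so blur tails
contaminate neither statistic.  Segmentation is deterministic; a flat
image, a missing cell body, a missing nucleus, or foreground/background
contrast below 1.2× raises a structured segmentation error.

## Per-cell statistic

`probeSignal()` is the **ratio of background-subtracted means** over a
region, not the mean of pixel ratios: low-intensity pixels make pixel
ratios unstable, whereas the ratio of means is the maximum-likelihood
estimate under the Poisson model and is exactly invariant to a constant
offset supplied as the background.  The per-cell crowding statistic is
`relativeProbe = probeNE / probeCyto`.  Regions smaller than 50 px set
a QC flag rather than failing the cell.

Group summaries use the n−1 SD and type-7 (linear interpolation)
quartiles with the 1.5·IQR outlier rule, matching the boxplot
presentation conventional for these comparisons.  Treatment comparisons
normalize treated probe signals to the reference-group mean and test
the unnormalized values with a two-tailed Welch t-test
(`stats::t.test`, unequal variances); the test's direct
Welch–Satterthwaite formula serves as an independent oracle in the test
suite, together with a 2000-replicate null simulation of its type-I
error.

# Mitotic time lapse

## Generator

Two elliptical chromosome masses overlap before anaphase onset and
become disjoint at the onset frame, then separate at a constant
velocity (2 px/frame default) inside a cytoplasmic disk with true
extracellular background outside.  Frames are 2 min apart; the default
stack has 3 pre-onset frames and covers 0–30 min after onset.  The
chromosome-surface rim band accumulates probe density with first-order
kinetics

$$ L(t) = 1 - e^{-k (t - t_0)} \quad (t \ge t_0), $$

optionally multiplied by a telophase decay
$e^{-k_d (t - t_{telo})}$ for early-assembling classes.  The rim
crowder concentration ramps from `concStart` to `concPlateau` in
proportion to the **undecayed** curve, so crowding persists when early
assemblers dissociate — making "crowding follows assembly, then
outlives it" reproducible by construction while the pipeline stays
blind to it.  Kinetic presets (all k = ln2/3 min⁻¹, ramp
100→180 mg/mL): `early_assembler` (t₀ = 1 min, telophase decay from
10 min), `pom121_like` (t₀ = 3), `late_assembler` (t₀ = 10); their
analytic half-max times t₀ + ln2/k are 4, 6 and 13 min.

## Quantification

Anaphase onset is the first frame whose thresholded chromosome mask
splits into ≥ 2 components with centroid distance > 10 px, persisting
for ≥ 2 consecutive frames (a one-frame spurious split is ignored); a
manual onset override is a first-class argument because real data may
lack a clean split.  Per frame, the chromosome-free shell (> rim
width + 8 px from the masses) is split by Otsu into cytoplasm and
extracellular background; backgrounds are per-channel medians of the
background class, re-estimated every frame.  The localization signal is
the relative nuclear localization `RNL = (rim − bg)/(cyto − bg) − 1`,
clipped at 0 — a rim/cytoplasm excess ratio.  Any affine rescaling of
this trace leaves the extracted half-times unchanged, so downstream
results do not depend on the exact RNL convention.  The probe series is
the rim A/D over cytoplasm A/D, normalized to the onset frame (exactly
1 at time 0).  The chromosome area series (thresholded mask area,
normalized to onset) is the control that distinguishes dissociation
from decondensation; frames without chromosome signal become flagged
gaps, not errors.

## Half-time extraction

The half level is the midpoint `(max + min)/2` over the post-onset
window.  The extreme on the **target** side (maximum of a rising trace,
minimum of a falling one) comes from a centred 3-frame moving average:
for saturating traces this is the plateau and resists noise spikes, and
for telophase-decaying classes it captures the smoothed peak — a single
convention that keeps the extracted half-max within half a frame of
t₀ + ln2/k for every kinetic preset.  The extreme on the onset side is
taken from the raw series, which is exact by construction (probe = 1 at
time 0; localization starts at 0).  The earliest crossing is located by
linear interpolation between adjacent raw frames; a step from 0 to 1
between frames therefore yields the midpoint of the two frame times.  A
trace that never crosses its half level (e.g. a probe signal that does
not change) returns an unrecoverable flag, not an error.  The
convention identifier is recorded in every half-time output.

# Validation scales and what it shows

The test suite and the acceptance script run at the study's own desk
scale: 20 phantoms per interphase condition (256×256 px, Poisson
noise), 20 immunostain pairs (treated rim density 0.70× intact,
washed-out cytoplasm at 0.1× density emulating digitonin
permeabilization), one noisy early-assembler stack (19 frames of
256×256×3), noise-free kinetic traces sampled every 2 min over 0–30
min, 200 replicate calibration fits, and 2000 null replicates for the
Welch type-I error.  Unit tests reuse the same generators at 160 px /
128 px to stay fast; at that scale the rim band is coarser relative to
the PSF, and the noise-free segmented pipeline is held to 0.015 instead
of the 0.01 used at full scale.

Passing these tests shows that the pipeline recovers the parameters of
data generated by its own declared model — geometry, optics and noise
included — and that its statistics are internally consistent.  It does
not show robustness to everything real microscopy adds: out-of-focus
light and 3-D sectioning, chromatic mis-registration, photobleaching,
autofluorescence, cell crowding and motion, NPC punctae from
overexpression, or donor bleed-through between detection bands.  The
generator also ties rim concentration to assembly by a linear ramp,
which real reassembly has no obligation to follow; concentration-scale
statements for real images require a user-supplied calibration curve.

# Degenerate inputs and numerical edges

* Bands with no grid point raise a band-out-of-range error, never a
  silent 0; zero spectra integrate to 0.
* `quenchFactor()` rejects negative concentrations; fits with fewer
  than 3 distinct concentrations are refused.
* Welch tests with n < 2, or two constant samples with different
  means, raise errors; two identical constant samples return t = 0,
  p = 1.
* Single-cell summaries report NA SD and collapsed quartiles.
* Identical seed + config reproduce every phantom bit for bit, and the
  generators restore the caller's RNG state.
* TIFF pages store counts divided by 65535 as 32-bit floats (the
  scale is recorded in the JSON sidecar), round-tripping at ~1e-7
  relative error.

# Known limitations

* 2-D only; no 3-D stacks or axial PSF.
* One cell per frame (largest-component fallback otherwise); no
  tracking across large displacements.
* No mitotic-phase classification beyond anaphase-onset detection.
* The quench model is a two-parameter phenomenological map; probes
  with non-linear quench curves would need a different `model` form in
  the calibration layer.
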