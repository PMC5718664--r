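---
title: "Methods: CATPHAN image-quality metrics and the synthetic scan generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CATPHAN image-quality metrics and the synthetic scan generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`catphanqa` automates the image-quality workup of CATPHAN-504 phantom scans
from linac-mounted cone-beam CT (CBCT) systems — Elekta's XVI and Varian's
OBI — as used in image-guided radiotherapy QA.  It covers six measurements:
pixel-value stability versus tube output (total mAs), noise,
contrast-to-noise ratio (CNR), the uniformity index (UI), high-contrast
(line-pair) resolution, and low-contrast detectability.  Because real
multi-protocol scan series are expensive to acquire (and no public series
exists for these systems), the package pairs the analysis code with a
synthetic CATPHAN scan generator whose ground truth is known exactly, so
every estimator can be validated end to end.

Out of scope by design: dosimetry, projection acquisition and tomographic
reconstruction, scatter and beam-hardening physics (the uniformity artifact
is parametric, not physical), ring/ghost artifacts, and the CTP515
sub-slice targets.

## The measurements

All measurements run on CT numbers obtained from stored DICOM pixels via
the rescale mapping

\[ \mathrm{CT} = \mathrm{pix} \times \mathrm{RescaleSlope} +
   \mathrm{RescaleIntercept}. \]

Both emulated systems use slope 1; the intercept is −1000 for OBI-like and
−510 for XVI-like exports.  With slope 1, pixel-value differences equal HU
differences, which is why the metrics below are well-defined even on XVI
scans whose absolute pixel values are not calibrated CT numbers.

Statistics are taken in circular ROIs of 6 mm diameter (small enough to sit
fully inside the 12 mm sensitometry inserts, and small enough that the
radial uniformity artifact does not inflate the standard deviation).  An
ROI comprises the voxels whose centres fall inside the circle; on a 1 mm
grid a 6 mm ROI holds 24–32 voxels depending on grid phase.  Standard
deviations use the n−1 denominator.

* **Noise** (CTP486): the mean of the standard deviations in five ROIs —
  one at the phantom centre, four at 0°/90°/180°/270° at 70% of the
  phantom radius.
* **CNR** (CTP404): \((S_\mathrm{ROI} - S_\mathrm{BG}) / \sigma_\mathrm{BG}\)
  on the polystyrene insert, the lowest-contrast material (−35 HU nominal),
  against a water-equivalent background ROI.  The sign is kept, so ideal
  scans give negative CNR.
* **Uniformity index** (CTP486):
  \( \mathrm{UI} = S_\mathrm{peripheral} - S_\mathrm{centre} \) (HU), with
  the four peripheral ROI means averaged (a `aggregate = "max"` option uses
  the most deviant ROI instead).  UI > 0 indicates cupping, UI < 0 capping;
  |UI| below a 5 HU tolerance is reported uniform.
* **Pixel-value stability** (CTP404): per-insert ROI means across an mAs
  series, summarized by the range (max − min, HU) per insert.
* **High-contrast resolution** (CTP528) and **low-contrast detectability**
  (CTP515) replace visual readings with explicit rules, described below.

Metrics are computed on the central slice of each module by default; every
measurement accepts `n_slices` to average 3 (or more) adjacent slices,
which reduces estimator variance without changing expectations.

### ROI placement choices

The phantom centre is found automatically: the slice is thresholded at its
minimum plus 10% of its dynamic range, the largest connected foreground
component is kept (discarding isolated noise voxels in the surrounding
air), and its centroid is used.  Everything is relative to the slice
content, so the locator — and therefore the CNR and UI, which difference
ROI means — is exactly invariant under global additive shifts of the pixel
values.  That matters for XVI scans, whose values drift with mAs.

Positions the phantom documentation leaves open are fixed, documented
choices here, all configurable: peripheral ROIs at 70% of the phantom
radius (70 mm bare, 112 mm with the body annulus); the CNR background ROI
at 30 mm radius, midway in angle between the first two inserts; CTP404
inserts equally spaced on a 60 mm-radius circle.  The metrics depend only
on ROI/target correspondence, not on absolute angles.

### Resolution scoring

Each of the 21 bar groups (1–21 lp/cm; bar width \(5/f\) mm; four line
pairs per group in the synthetic layout) is scored from the voxels inside
its region.  Voxels are classified bar/gap by the nominal pattern, and the
modulation is

\[ M_f = \frac{\overline{\mathrm{bar}} - \overline{\mathrm{gap}}}
              {\text{nominal bar contrast}} . \]

A group is *resolvable* when all four conditions hold:

1. \(f\) does not exceed the sampling Nyquist bound \(10/(2\,\mathrm{pitch})\)
   lp/cm, rounded half-up to an integer — a sampled image cannot represent
   faster patterns, only aliases of them;
2. \(M_f \ge 0.2\) (configurable threshold);
3. the bar−gap difference exceeds twice the image noise;
4. the dominant DFT frequency of the group's profile, binned at the pixel
   pitch along the pattern direction, is within 30% of nominal.

Condition 4 rejects aliased patterns: above Nyquist, partial-volume
sampling still leaves 20–40% apparent modulation, but the pattern is
reproduced at the alias frequency, which no observer would call resolved.
The reported maximum uses a first-failure rule (stop at the first
unresolvable group, no skipping), mirroring how bar gauges are read.  On
noiseless synthetic scans this scorer reports 5 lp/cm at 1 mm pitch and
6 lp/cm at 0.88 mm — the pixel-pitch-limited behaviour expected of these
reconstructions.  The 0.2 threshold and 30% tolerance cannot be fixed by
human-observer data, so they are explicit, documented defaults.

### Low-contrast scoring

Each supra-slice disc (three contrast levels — 1.0%, 0.5%, 0.3% of the
1000-HU scale, i.e. 10/5/3 HU — with nine diameters 2–15 mm per level)
gets a Rose-criterion detectability index

\[ d = \frac{|S_\mathrm{disc} - S_\mathrm{local\,BG}|\sqrt{n}}{\sigma}, \]

with \(n\) the disc-ROI voxel count and \(\sigma\) the image noise; the
disc is counted visible when \(d \ge k_\mathrm{Rose} = 3\).  The disc ROI
is 70% of the disc diameter, capped at 6 mm and floored at 1.5 pixels so
even the 2 mm disc contains at least one voxel centre.  The local
background ROI sits at the same radius, offset midway towards the next
disc.  Counts are reported per contrast level (0–9 each).

## The synthetic scan generator

`simulate_scan()` composes a fixed pipeline; the order is part of the
contract:

1. **render** — each voxel gets the nominal CT number of the material at
   its location, with partial volume handled by area-weighted 4×-per-axis
   supersampling; air (−1000 HU) outside the phantom;
2. **uniformity artifact** — in-phantom voxels at radius \(r\) gain
   \(A\,(r/R)^p\) HU (\(p = 2\) by default); \(A > 0\) produces cupping
   (UI > 0), \(A < 0\) capping;
3. **drift** — each material class gains
   \(\mathrm{offset} + \mathrm{slope}\cdot\log_2(\mathrm{mAs}/\mathrm{mAs}_\mathrm{ref})\)
   HU, the simplest monotone model of the mAs-dependent detector-response
   drift seen on XVI; OBI-like presets use an all-zero map;
4. **blur** — isotropic in-plane Gaussian PSF of stated FWHM (via
   `EBImage::gblur`), standing in for reconstruction and post-filtering
   resolution loss;
5. **noise** — zero-mean white Gaussian noise with
   \(\sigma = k/\sqrt{\mathrm{mAs}}\) HU, the reconstructed-domain
   signature of quantum noise.  Noise is always last, so it stays
   spatially uncorrelated;
6. **encoding** — HU are stored as unsigned 16-bit integers,
   \(\mathrm{pix} = \mathrm{round}(\mathrm{HU} - \mathrm{intercept})\),
   clamped at 0.  Quantization changes values by at most 0.5 HU; the XVI
   intercept of −510 means values below −510 HU saturate (notably the air
   insert), consistent with that system's uncalibrated export.

Ground truth (A, p, k, per-setting σ, PSF, drift map, seed) is written to
a JSON sidecar manifest next to the DICOM series, so recovery tests are
self-describing.  `simulate_mas_series()` renders the phantom once per
series — as a physical series is one setup with several exposures — and
applies the per-setting stages per scan.

### Default presets and why

The presets are calibrated once, from the study conditions the emulated
systems exhibit, not tuned to tests:

* **Noise**: \(k = 25\sqrt{\min \mathrm{mAs}}\) per protocol, i.e. σ is
  25 HU at the protocol's lowest setting and falls as \(1/\sqrt{\mathrm{mAs}}\).
* **Uniformity**: \(A = \mathrm{UI}_\mathrm{target}/0.49\), because with
  peripheral ROIs at 70% radius and \(p = 2\), \(\mathrm{UI} = A\,(0.7)^2\)
  exactly (the ROI-averaging curvature terms cancel).  The per-protocol UI
  targets are the protocol-average values reported for these systems —
  e.g. −20.78 HU for OBI full-fan (capping), +11.58 HU for OBI half-fan
  with the bare phantom, −288.67 HU for the XVI chest protocol with the
  body annulus (strong capping from over-correction).
* **Drift**: XVI presets drift all in-phantom classes by −160 HU per
  doubling of mAs — spanning > 300 HU across each protocol's 4× mAs
  range, the magnitude class reported for that system — while OBI presets
  do not drift.
* **PSF**: 1.5 mm FWHM for XVI versus 0.8 mm for OBI, reflecting the
  heavier post-reconstruction filtering that makes XVI images smoother
  (and less able to show low-contrast discs) at comparable settings.

### What the generator does and does not emulate

It reproduces the *reconstructed-domain behaviours* that the metrics
respond to: nominal insert contrasts, mAs-dependent Gaussian noise, a
radial cupping/capping profile, monotone per-class pixel drift, and
pitch-limited bar visibility.  It does not simulate projections, scatter,
beam hardening, bow-tie filtration, detector lag, or ring/ghost artifacts;
the drift model is monotone, so the non-monotone large-phantom behaviours
reported for some XVI protocols (high-density inserts rising then falling
with mAs) are not produced by the default presets, though per-class custom
drift maps can express arbitrary monotone variants.  Consequently, passing
recovery tests demonstrates that the estimators measure what they claim on
images with known truth — not that the generator predicts any particular
scanner's absolute performance.

## Numerical choices and degenerate inputs

* Supersampling is 4× per axis by default; rendering is deterministic, so
  identical configurations give bit-identical series (given the same seed).
* Slice ordering in `read_series()` follows axial position, not file name;
  duplicate positions are an error rather than a silent choice.  Missing
  rescale tags fall back to slope 1 / intercept 0 with a warning.
* Half-up rounding is used for the integer lp/cm Nyquist bound (so
  5.68 → 6).
* An all-air image raises a phantom-not-found error; a zero-noise
  background makes CNR undefined (error) and low-contrast detectability
  saturate (every disc visible).
* ROIs that would leave the image raise an error; ROI statistics require a
  configurable minimum voxel count (5 by default, 1 for the smallest
  low-contrast discs).

Test and validation problem sizes are deliberately desk-scale: 1 mm
renders of single modules (220×220 pixels, 1–3 slices per module), the
0.47 mm OBI full-fan grid only where the pitch matters, and mAs series of
4–6 settings — large enough that every estimator's sampling error is well
inside its stated tolerance (tolerances in the test suite are set from
standard-error budgets at 3 SE or wider), small enough to run in seconds.

## Known limitations

* The DICOM layer targets uncompressed single-frame axial CT (explicit or
  implicit VR little endian) — the dialect these systems export — not the
  full standard (no compressed syntaxes, multi-frame objects, or non-axial
  orientations).
* The resolution and low-contrast rules are automated surrogates for what
  are, on real phantoms, human-observer readings; their thresholds are
  documented defaults, not fitted constants, and absolute agreement with a
  particular observer is not claimed.
* Uniformity-artifact recovery is exact for \(p = 2\) by construction of
  the ROI layout; other exponents recover the integrated (not peak)
  profile.
* XVI's unsigned-with-offset encoding saturates below −510 HU, so the air
  insert cannot drift; statistics on real XVI exports share this floor.
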