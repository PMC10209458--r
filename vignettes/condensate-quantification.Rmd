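---
title: "Quantifying synaptic protein condensates: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synaptic protein condensates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`punctate` quantifies the nanoscale organization and activity-dependent
dynamics of phase-separated protein condensates at presynaptic terminals from
fluorescence imaging. Synaptic vesicle clusters are held together in part by
liquid–liquid phase separation of soluble proteins such as synapsin and
endophilin; the package implements the image-analysis computations used to
characterize such condensates — 3D single-molecule reconstruction and
object-based two-color colocalization of protein clusters, and time-lapse
statistics of condensate dispersion, reassembly and FRAP — together with a
synthetic-data generator that produces every input with recorded ground
truth. This vignette explains the models, the parameters that matter, the
numerical choices, and what the synthetic validation does and does not show.

```{r setup, message = FALSE}
library(punctate)
```

## The optical model and the synthetic blinking movie

Single-molecule movies are generated from an `optics_model()`: a camera with
200 nm pixels, an in-focus Gaussian PSF of sigma `w0 = 180` nm, and a
cylindrical-lens astigmatism under which the fitted Gaussian widths in x and
y follow quadratic defocus curves with opposite-sign focal offsets,

$$ w_x(z) = w_0 + a\,(z + \gamma)^2, \qquad w_y(z) = w_0 + a\,(z - \gamma)^2 . $$

The width difference $w_x - w_y = 4 a \gamma z$ is then linear in $z$, so it
is strictly monotone (the property every astigmatic z-calibration needs) and
analytically invertible, which makes the whole z path checkable against a
closed form. No published PSF model accompanies the analysis this package
re-implements, so the quadratic form — the conventional small-defocus
expansion — is our choice. The defaults $\gamma = 350$ nm and
$a = 6\times10^{-4}\,\mathrm{nm}^{-1}$ give a width-difference slope of
about 0.84, a typical operating point for astigmatic 3D imaging that yields
roughly 10 nm axial precision at the default photon budget of 3,000
photons/emitter over 10 photons/pixel background. Noise is Poisson by
default (optional Gaussian read noise); EMCCD gain statistics are not
modeled because no photon calibration is available for the original
instrument — synthetic noise levels are chosen to reach realistic
localization precisions, not to match a specific camera.

Per frame, a Poisson number of emitters (default mean 1) is activated
uniformly inside the ground-truth cluster of the frame's scheduled channel;
frames alternate between two activation channels, as in two-color
direct STORM with alternating activation lasers. Emitters are rendered with
the pixel-integrated Gaussian (error-function) profile, so photon flux is
conserved exactly and the fitting model class matches the generative model
class. Bright stationary fiducial beads and a per-frame drift trajectory can
be added; drift displaces emitters and fiducials alike, while the truth
table records pre-drift positions.

**Activation density.** About one activation per frame is the sparsity at
which single-emitter fitting is valid for a diffraction-limited synapse: two
simultaneous activations in a ~200-nm cluster always merge into one spot at
a PSF sigma of ~200 nm. The localization filter therefore includes an
amplitude ceiling at 1.5x the photon budget, which rejects merged
two-emitter fits (their fitted photon count is close to twice the budget).
With 10,000 frames — the per-cycle frame count of a typical two-color STORM
acquisition — about 5,000 emitters activate per channel and roughly 1,800
clean single-emitter localizations per channel survive filtering, enough to
reconstruct clusters of ~110 nm radius at full voxel occupancy.

## Localization, z assignment, drift correction

Frames are smoothed with a normalized 2D Gaussian (radius 1 pixel, with the
sigma = radius/2 convention used throughout). Candidates are local maxima
above `mean + 4 SD` of the smoothed frame, separated by at least one
fit-window radius, with ties broken toward the smaller row-major index.
Each candidate is fit on a 7x7-pixel window (the PSF sigma is about one
200-nm pixel, so 7 pixels covers ±3 sigma at focus) by Levenberg–Marquardt
least squares of a pixel-integrated elliptical Gaussian plus offset.
Rejection criteria (amplitude floor, center inside the window, widths away
from the optimizer bounds) are engineering choices: the original analysis
software does not state its thresholds.

The z coordinate comes from monotone piecewise-linear interpolation of
$w_x - w_y$ over the calibration nodes; width differences outside the
calibrated range mark the localization as excluded rather than
extrapolating. No refractive-index rescaling of z is applied.

Drift is estimated by tracking each fiducial's nearest accepted localization
per frame, averaging displacements over fiducials, and smoothing with a
centered moving average (window 100 frames) whose window shrinks
*symmetrically* near the trace ends. The symmetric shrinkage matters: a
one-sided window at the last frame would bias the endpoint of a linear
drift by ~half a window of drift, which at 0.1 nm/frame is a 5 nm error all
by itself. The corrected table subtracts the per-frame displacement;
correction is idempotent to well under 2 nm RMS.

## Voxelization, segmentation and colocalization metrics

Localizations are binned onto a 10-nm voxel grid (half-open bins: a
coordinate exactly on an interior edge goes to the higher bin). Each
channel's volume is smoothed with a 3D Gaussian filter of radius 2 voxels
(20 nm) and binarized with Otsu's algorithm on a 256-bin histogram computed
per channel; the histogram bins rescale with the data, so the mask is
invariant under positive affine rescaling of intensities. Positive voxels
are split into connected components (26-neighborhood by default,
configurable to 6 — the published description says only "connected
components", and 26 is the permissive convention); the largest component is
the major cluster and all smaller ones are discarded, with ties broken
toward the component containing the smallest voxel index in scan order.

Two conventions in the smoothing step are genuinely open and therefore
configurable: the Gaussian "radius" of 2 voxels is interpreted as
sigma = radius/2 = 1 voxel (the convention of the software framework the
original authors used), with sigma = radius selectable; and Otsu is applied
to each channel's own histogram rather than a joint one.

From the two major-cluster masks the package reports directional Manders
coefficients (fraction of the reference cluster's voxels positive in the
other channel — the object/voxel-based variant, not intensity-weighted),
cluster volumes in voxels and nm³, their ratio, and the Euclidean distance
between the centers of mass (mean voxel coordinates). All metrics are
translation invariant and axis-permutation equivariant; Manders of a mask
with itself is exactly 1 and with a disjoint mask exactly 0.

## Dispersion kinetics, FRAP, and the CV metric

Time-lapse puncta analysis uses circular ROIs of diameter 1.08 um (pixels
whose centers fall within the radius), sampled at 0.2 Hz. The normalized
dispersion series is $\Delta F = (F - F_{t=15})/F_0$ over the stimulation
window 15–75 s and the recovery series $(F - F_{t=75})/F_0$ over 75–320 s,
so each series is exactly zero at its reference time. $F_0$ is taken as the
mean of all pre-stimulus samples (t < 15 s); the published formula writes
$\Delta F (F - F_{t=15})/F_0$ without defining $F_0$, and the pre-stimulus
mean is the standard reading — `f0 = "at_onset"` selects the alternative.
The mobile fraction is the magnitude of the dispersion series at the single
time point t = 75 s, per the literal description (not an average around it).

Both windows are fit with the monoexponential $y = A(1 - e^{-t/\tau})$ by
bounded Levenberg–Marquardt least squares, time re-zeroed at the window
start, initialized at $A_0 =$ the series endpoint and $\tau_0 =$ the first
crossing of $(1 - 1/e) A_0$, with $\tau$ bounded in $(0, 10\times]$ the
window. A fitted time constant longer than the imaging window cannot be
resolved within the experiment and is flagged `excluded`, mirroring the
published exclusion rule.

FRAP traces are normalized affinely so the pre-bleach mean maps to 1 and the
bleach-point value to 0; the normalized trace is invariant under any
positive affine distortion of the raw intensities, and the recovery fit's
plateau estimates the mobile fraction.

The dispersion state of fixed images is scored by the coefficient of
variation along a 5-pixel-wide polyline over axon-like structures:
CV = SD/mean of the band samples ("signal variability" is taken as the
standard deviation — the standard CV definition). Unit steps along the line
with integer perpendicular offsets and nearest-pixel lookup define the band.
Preprocessing (rolling-ball radius 50 px, Gaussian sigma 1.0) is applied in
the fixed-image pipeline but is off by default in `cv_along_line()` so the
metric itself stays a pure sample statistic. High CV means punctate
(condensed), low CV means dispersed; redistributing punctate intensity
uniformly while conserving the total strictly lowers the CV.

The rolling-ball background is implemented as the grayscale morphological
opening with a disc structuring element — the envelope of a ball rolled
under the intensity surface; registration of time-lapse stacks is
translation-only (droplets and boutons do not rotate on these timescales),
by FFT cross-correlation with parabolic subpixel refinement.

## The synthetic generator as a study design

The generator's defaults are the study conditions: 200-nm pixels, 128x128
fields, 10-nm voxels, 3,000 photons/emitter, background 10, alternating
channels, 0.2-Hz trace sampling over 0–320 s with stimulation at 15–75 s,
noise sigma 0.02 on normalized traces, and dispersion/recovery parameters
(amplitudes 0.18 and 0.36; tau_d 24.8 and 23.5 s; tau_r 105.9 and 107.8 s;
about two dozen traces per group) matching the fitted values reported for
the two presynaptic proteins whose dynamics motivated the package. Recovery
studies use two spherical clusters of ~110 nm radius offset by 50 nm whose
target overlap fraction is dialed in by searching the second sphere's
radius against the voxel-exact truth.

What passing the synthetic recovery shows: the chain of localization,
z assignment, drift correction, filtering, voxelization, segmentation and
metric computation is unbiased to within ±0.05 in overlap fraction and
±5 nm in center-of-mass distance under realistic photon statistics. What it
does not show: robustness to dye photophysics (blinking duty cycles,
bleaching), activation-intensity ramps (the real acquisitions ramp the
activation laser; the generator holds the rate constant), sample-dependent
background structure, chromatic misregistration, or segmentation behavior
on non-spherical cluster shapes. Those are properties of real data the
synthetic model deliberately does not emulate.

```{r recovery-example, eval = FALSE}
# one full-pipeline recovery run (about 2 minutes)
m <- storm_recovery_study(overlap = 0.5, seed = 1)
m[, c("manders_a_in_b", "truth_overlap_a_in_b", "com_distance_nm")]
```

## Numerical choices and degenerate inputs

* Gaussian smoothing uses kernels truncated at 4 sigma, normalized to unit
  mass, with replicate padding, so constant inputs are preserved exactly.
* Otsu on a constant volume, an empty voxelization, an all-zero line
  profile, a zero-mean CV band, and a degenerate FRAP normalization
  (pre-bleach mean equal to the bleach value) are all hard errors rather
  than silent NaNs.
* Component-size ties, candidate-intensity ties and equal-maxima plateaus
  all break deterministically toward the smallest scan-order index.
* Every stochastic operation takes an explicit integer seed and is
  bit-reproducible from (specification, seed); `run_pipeline()` reruns are
  byte-identical.
* Problem sizes in the test-suite recovery studies (10,000 frames, ~1,800
  accepted localizations/channel, 24 traces/group, 1,000 spot fits) are the
  package's chosen validation scale: large enough that recovery error is
  dominated by method bias rather than sampling noise, small enough to run
  routinely.

## Known limitations

* Single-emitter fitting only: overlapping activations are rejected, not
  deconvolved (no multi-emitter or maximum-likelihood fitting).
* The localization engine assumes an axis-aligned elliptical Gaussian PSF;
  aberrations beyond astigmatism are not modeled.
* Synapse ROIs are inputs (bounding boxes), as in the original analysis —
  there is no automatic synapse detection.
* The CV metric and droplet colocalization operate on single images;
  they inherit whatever preprocessing the caller applies upstream.
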