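---
title: "Non-contact photoacoustic imaging with a homodyne LDV: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-contact photoacoustic imaging with a homodyne LDV: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(paldv)
```

`paldv` models the complete measurement chain of a non-contact
photoacoustic imaging experiment read out by an on-chip homodyne laser
Doppler vibrometer (LDV): pulsed light absorbed in an ink-filled channel
inside a silicone (PDMS) slab launches an acoustic wave; the wave reaches
the slab surface; an interferometer reads the surface motion as I/Q
quadrature signals; signal processing turns those into calibrated surface
pressure; and a time-reversal solver turns a line scan of pressure traces
into a 2D image of the initial pressure. This vignette records the models,
the parameter choices, and the design decisions behind each stage.

## Acoustic model

The wave engine integrates the first-order acoustic system for pressure
$p$ and particle velocity $\mathbf{v}$ in a heterogeneous 2D medium,

$$\partial_t \mathbf{v} = -\frac{1}{\rho}\nabla p, \qquad
  \partial_t p = -\rho c^2 \nabla\!\cdot\!\mathbf{v},$$

on a staggered grid (pressure at cell centres, velocity components on cell
faces) with leapfrog time stepping at CFL number 0.3. The scheme is the
standard explicit solver for this class of problem; it supports both the
forward emission run and, unchanged, the time-reversed re-emission used
for image reconstruction.

Assumptions: 2D propagation (the channels are long cylinders perpendicular
to the imaging plane), no shear waves (soft solids), no absorption, and
instantaneous (stress-confined) photoacoustic generation — the initial
condition is a pressure distribution at $t=0$ with the medium at rest.

**Medium.** PDMS has sound speed 1020 m/s; the water–ink channel interior
is water-like at 1500 m/s. Density is 1000 kg/m³ everywhere so that the
sound speed alone sets the acoustic impedance: 1.02 MRayl for PDMS and
1.5 MRayl for the channel, matching both printed impedances with a single
density. The channel's interior sound speed is not separately reported;
water-like properties are the natural choice and are consistent with the
observed early arrival of the wave transmitted *through* the channel.

**Boundaries.** The detection surface ($z=0$) and the slab backside are
pressure-release ("soft") boundaries, implemented as Dirichlet $p=0$ rows:
appropriate for a solid/air interface, and the origin of both the backside
echo and the mirror artifact in reconstructions. Lateral edges carry a
40-cell absorbing sponge (smooth cubic per-step damping ramp) emulating a
slab of unbounded width.

**Observable.** An LDV measures the motion of the surface itself. The
solver records the normal particle velocity half a cell inside the soft
surface (pressure is identically zero *on* it); displacement is the
cumulative time integral. Because the incident wave reflects with inverted
polarity, the free surface moves at twice the incident particle velocity,
which is why incident pressure is recovered as $p = \tfrac{Z_s}{2}u$ with
$Z_s = 1.02$ MRayl.

**Grids and rates.** Default $dx = 20\ \mu$m gives $\ge 10$ cells per
wavelength at 5 MHz (the processing band edge). The solver's internal step
is CFL-driven ($\approx 4$ ns); outputs are resampled onto the 65 MS/s
acquisition clock by cubic-spline interpolation, which is accurate here
because the solver rate oversamples the acoustic band by a factor $>20$.
`build_medium()` takes the resolution criterion as an explicit `f_max`
argument and refuses grids coarser than 10 cells per wavelength at that
frequency; analyses that intentionally work in a lower band (e.g. quick
exploratory runs) must say so by passing a smaller `f_max`.

## Synthetic data: what is emulated

The generator stands in for the laboratory: it defines the study
conditions rather than adapting to them.

* **Phantom**: 10–13 mm PDMS slab (12 mm default), 2 mm-diameter channels
  at 5.8–9.6 mm depth, ink concentration 0.01–1 % with the 0.1 % reference
  extinction of 12.5 cm⁻¹ scaling linearly (Beer–Lambert).
* **Initial pressure**: uniform across each channel disc, amplitude
  $\mu_a \times$ `fluence_scale` (Pa·cm). The default 1000 Pa·cm places
  surface signals in the mm/s velocity range. A single scalar per channel
  stands in for the real, divergent illumination profile; fluence
  heterogeneity across the disc is not modelled.
* **I/Q synthesis**: $\theta'(t) = 4\pi d(t)/\lambda + (\theta_1-\theta_0)$
  at $\lambda = 1550$ nm, rendered as
  $I = g_I R\cos\theta' + o_I$, $Q = g_Q R\sin(\theta'+\varepsilon) + o_Q$
  with locus radius $R = 2\mu|rm|$, independent white noise per segment,
  65 MS/s sampling, and 1 kHz triggering. A damped 20 MHz ring-down in the
  first ~0.3 µs of each segment reproduces the electromagnetic
  interference of the excitation pulse firing at $t=0$; it is on by
  default so the processing chain demonstrates robustness to it.
* **Scanning**: 125 µm pitch, 80 positions over ~1 cm, 1 s of triggered
  averaging per position (1000 segments at 1 kHz). An optional log-normal
  per-position collection-efficiency factor mimics the observed variation
  in collected optical power (off by default so oracles stay exact).
* **Detection bandwidth**: the hardware's ~3.5 MHz response can be
  emulated by low-passing the displacement before synthesis; it is off by
  default for clean round-trip oracles.

What the generator does **not** emulate: optical speckle and surface
roughness, amplifier nonlinearity and saturation, 3D acoustic divergence
(2D cylindrical spreading is built in), frequency-dependent attenuation,
and fluence shadowing inside strongly absorbing channels. Passing tests
therefore validate the processing chain against its own generative model,
not against every hardware effect; the hardware-specific lab numbers
(noise floors, absolute sensitivities) are outside what synthetic data can
certify.

## Demodulation chain

Per segment: Heydemann-style ellipse correction (translate by the fitted
centre, rotate by the tilt, rescale both semi-axes to 1, rotate back),
four-quadrant `atan2`, greedy $2\pi$ unwrapping, and conversion
$d = \lambda\,\Delta\theta'/4\pi$. Segments are demodulated *before*
trigger-aligned averaging: averaging raw I/Q first would bias the phase
through the arctan nonlinearity. Velocity is the central-difference
derivative followed by a zero-phase (forward–backward) 4th-order
Butterworth low pass at 5 MHz — the cutoff is prescribed, the
family/order is this package's choice, and zero-phase filtering avoids
group-delay bias in arrival times. Pressure is $Z_s u/2$; envelopes are
analytic-signal magnitudes.

The calibration ellipse comes from a reference record of a sinusoidal
vibration larger than $\lambda$ (locus closes). The fit is the direct
least-squares conic fit constrained to an ellipse, which is exact on
noiseless data; a quadrature error $\varepsilon$ appears as ellipse tilt
and is absorbed by the correction. Because any linear distortion of the
unit circle composed with its fitted correction is an orthogonal map, the
corrected phase equals the true phase up to an additive constant —
which drops out of $\Delta\theta'$; this is why the end-to-end identity
holds at numerical precision for gain ratios up to 1.5, offsets up to 0.3
radii and $\varepsilon$ up to 10°.

Numerical details: samples whose corrected I/Q radius falls below 0.05 are
flagged as dropouts, linearly interpolated in phase and counted; the first
sample of each averaged trace defines zero displacement (homodyne
detection only measures relative motion).

## Detector characterization

The noise-equivalent-velocity (NEV) spectrum is the square root of the
one-sided Welch PSD (Hann window, 50 % overlap, $2^{14}$-sample segments —
the method is named in the literature, the settings are ours). Scaling is
density-normalized so that the band integral of the PSD equals the signal
variance (Parseval), making the band-integrated NEV, and NEP
$= \tfrac{Z_s}{2}\,$NEV, well defined. Sensitivity is the ratio of FFT
magnitude spectra of the same pulse seen by a candidate and a reference
detector, masked where the reference falls below 5× a running-median
noise-floor estimate; the 3 dB bandwidth is where that ratio drops
$1/\sqrt{2}$ below its sub-MHz plateau, with linear interpolation between
bins. SNR is the Hilbert-envelope maximum of the pulse divided by the RMS
of a pre-arrival noise window ([0.5 µs, arrival − 1 µs], which excludes
the $t=0$ interference transient); the envelope search can be windowed to
the pulse for the same reason.

## Time-reversal reconstruction

The recorded pressure traces are time-reversed and re-emitted as Dirichlet
pressure sources at the sensor cells (one row inside the soft surface) in
a *homogeneous* 1020 m/s medium — channel heterogeneity is deliberately
not modelled in reversal, matching the use of a single reported speed of
sound. The field at the final step is the initial-pressure estimate. In
envelope mode the Hilbert quadrature of each trace is back-propagated as
well and the point-wise magnitude of the two reconstructions is returned:
envelope detection in image space, nonnegative by construction. The
reconstruction medium keeps the soft detection surface but uses an
absorbing backside and a depth extent of twice the slab thickness, so the
backside echo in the data focuses where it appears to originate — at the
source depth mirrored about the backside. That mirror artifact is part of
the physics and is intentionally not suppressed.

`localize()` smooths the envelope image with a boxcar of radius equal to
the channel radius (a matched filter for the extended source) before
non-maximum-suppressed peak picking with suppression radius equal to the
channel diameter.

### Validation accuracy and a known bias

Forward-then-reverse round trips on compact sources localize to within two
grid cells. With homogeneous propagation, a 2 mm channel at 7 mm depth
localizes exactly, the backside mirror appears at the mirrored depth, and
channels at 5.8/7/9.6 mm reproduce their depths on the grid. When the
forward data instead include the physical 1500 m/s channel interior and
are reconstructed with the homogeneous medium, the imaged channel sits
about 0.3 mm shallow — half the through-channel time advance
$2\,\mathrm{mm}\,(1/1020 - 1/1500)\cdot 1020 \approx 0.64$ mm. This is
irreducible model mismatch of single-speed reconstruction, not an
implementation artifact (compact sources show no bias), and it applies
equally to any single-speed reconstruction of such data.

### Arrival-time statistic

For a uniform-pressure 2 mm disc at 7 mm depth in a homogeneous 1020 m/s
slab, the surface velocity is a packet spanning the edge arrivals
$(d\pm R)/c = 5.88$–$7.84$ µs with centre $d/c = 6.86\ \mu s \approx 7$
µs. The broadband Hilbert-envelope *peak* of that packet sits at its sharp
leading edge, ~5.9–6.0 µs, and stays there under 2 MHz–5 MHz low-pass and
band-pass detection models; an independent exact solution of the 2D disc
initial-value problem (polar-integral form) confirms the leading-edge
envelope peak at 5.89 µs. The acceptance script reports the envelope-peak
statistic as computed; readers comparing against a "≈ 7 µs" packet
arrival should use the packet-centre time of flight, which the package's
geometry exposes directly as `depth / 1020`.

## Problem sizes

Default production runs use $dx = 20\ \mu$m (about 600 × 780 cells for a
12 × 14 mm slab, ~4 ns steps). The test suite validates the solver physics
on those grids where the claim requires it (arrival time,
reflected-front splitting) and otherwise uses 40–50 µm grids with
correspondingly reduced `f_max`, sparse scans and tens-of-segment
averaging, which exercise identical code paths at a fraction of the cost.
The full-scale scan (80 positions × 1000 segments) is the configured
default of the pipeline and streams position-by-position to bound memory.

## Known limitations

* 2D only: out-of-plane divergence and finite channel length are not
  modelled; absolute amplitudes are not comparable to 3D experiments.
* No acoustic attenuation or dispersion in PDMS.
* Ellipse correction assumes a static distortion during a measurement;
  drifting offsets between calibration and measurement are not corrected.
* Single-speed time reversal carries the ~0.3 mm depth bias described
  above for strongly contrasting inclusions.
* The trace I/O is plain CSV (with YAML/JSON configuration); large
  acquisitions are better regenerated from their seed than stored.
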