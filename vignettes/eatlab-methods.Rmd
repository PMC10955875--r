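---
title: "Electroacoustic tomography with eatlab: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electroacoustic tomography with eatlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eatlab)
```

## The physical model

Electroacoustic tomography (EAT) images where electrical energy is
deposited in tissue during pulsed-field electroporation.  A nanosecond
high-voltage pulse applied to an electrode pair drives a current through
the conductive medium; the Joule heat launches a broadband ultrasound wave
through thermoelastic expansion, and a ring of detectors records it.  When
the pulse is short enough for both stress and thermal confinement
(a ~100 ns pulse versus microsecond-scale acoustic transit across the
heated region), the chain factorizes into four stages, each one module of
this package.

**Electric field (quasi-static).**  On the 2-D medium grid the potential
solves the conservation law \(\nabla\cdot(\sigma\nabla\varphi)=0\) with
the electrode discs held at their applied potentials.  The per-pulse Joule
dose is
\[
H(\mathbf r) \;=\; \sigma(\mathbf r)\,|E(\mathbf r)|^2\,\tau_{\mathrm{eff}},
\qquad E = -\nabla\varphi ,
\]
with \(\tau_{\mathrm{eff}}\) the integral of the normalized squared
voltage waveform — for a trapezoidal pulse of FWHM \(T\) and linear edges
of duration \(r\), \(\tau_{\mathrm{eff}} = T - r/3\) (95 ns for the
default 100 ns / 15 ns pulse), close to the FWHM as expected for a
near-square pulse.

**Initial pressure.**  Under confinement the deposited heat density maps
locally to pressure through the Grüneisen-like factor of the medium,
\[
p_0(\mathbf r) \;=\; \frac{\beta(\mathbf r)}
{\kappa(\mathbf r)\,\rho(\mathbf r)\,C_v(\mathbf r)}\,H(\mathbf r).
\]
The default muscle-like property set (σ = 0.5 S/m, β = 4×10⁻⁴ K⁻¹,
κ = 4.5×10⁻¹⁰ Pa⁻¹, ρ = 1050 kg/m³, C_v = 3600 J/(kg·K), v_s = 1497 m/s)
gives a Grüneisen-like factor of about 0.24, in the usual soft-tissue
range.  One heat capacity is carried per medium: the thermoacoustic
literature writes the confinement relation with \(C_v\) and the wave
equation source term with \(C_p\); for soft tissue the two differ by a few
per mille, far below every other model error here, so the package does not
distinguish them.  Likewise any electrical-to-thermal absorption fraction
is treated as folded into the Grüneisen-like factor rather than carried as
a separate coefficient.  Conductivity is treated as constant in time — at
high pulse counts the electroporation-induced conductivity rise saturates,
and resolving its dynamics is out of scope.

**Acoustic propagation.**  The forward model is the free-space retarded
Green's-function solution of the thermoacoustic wave equation evaluated at
each detector position \(\mathbf r_0\):
\[
p(\mathbf r_0, t) \;=\; \frac{1}{4\pi v_s^2}\,\frac{\partial}{\partial t}
\int d\mathbf r'\, \frac{p_0(\mathbf r')}{|\mathbf r_0-\mathbf r'|}\,
\delta\!\Big(t - \tfrac{|\mathbf r_0-\mathbf r'|}{v_s}\Big).
\]
Both the bare shell integral (`form = "as_printed"`) and its time
derivative (`form = "derivative"`, the default) are implemented.  The
derivative form is the physically complete solution and produces the
bipolar N-shaped pulse of a compact source; the integral form is retained
because it is the expression most often quoted and is useful for testing
(it is the analytically simpler object).  A 2-D source map is propagated
with the 3-D \(1/d\) spreading weight, consistent with a thin source slice
in the plane of the ring.

**Reconstruction.**  Universal back-projection (UBP) forms, per channel,
\[
b(t) \;=\; 2p(t) - 2t\,\frac{dp}{dt},
\]
and sums it over elements onto circular shells \(t = |\mathbf r -
\mathbf r_0| / v_s\) with uniform aperture weights (a hook for
solid-angle weights exists in the code).  A plain delay-and-sum (DAS)
beamformer is kept alongside as an independent cross-check; tests require
the two to agree on point-target positions.  An envelope option projects
the analytic-signal magnitude of \(b(t)\), which is the conventional
non-negative display for ring arrays.  Reconstruction deliberately reuses
the forward model's uniform sound speed: the experiments this toolkit
emulates used homogeneous phantoms, and sound-speed mismatch is not
modelled.

## The signal chain

Traces pass through the processing steps standard for RF ultrasound:

* **Zero-phase band filtering.**  Both the 6 MHz low-pass and the 2–6 MHz
  transducer response are applied in the frequency domain with
  raised-cosine transitions and exactly zero phase, so arrival times are
  never shifted.  The transducer response has a flat unity top with
  transitions *interior* to its 2–6 MHz support and identically zero gain
  outside it — the flat-top bell of a physical 5 MHz broadband probe.
  Frequency-domain filtering was chosen over high-order IIR filtering
  (`filtfilt`) because it gives an exact stopband floor and avoids the
  numerical fragility of order-8+ recursive filters.
* **Wavelet denoising.**  A periodized orthogonal Coiflet-3 DWT
  (implemented natively; the filter taps are the standard published
  constants, and the transform is tested for perfect reconstruction to
  machine precision) with the universal "sqtwolog" threshold
  \(\hat\sigma_j \sqrt{2\ln N}\), \(\hat\sigma_j\) estimated per detail
  level by the median absolute deviation.  The default is **hard**
  thresholding averaged over 16 circular shifts (translation-invariant
  cycle spinning).  Plain soft thresholding was evaluated first and
  rejected as the default: soft shrinkage biases the large in-band signal
  coefficients by the threshold itself and, on the package's own
  20 dB N-wave benchmark, plateaus around 32 dB output SNR, whereas
  hard thresholding with cycle spinning reaches 36–38 dB while remaining
  near-lossless on clean traces.  Soft thresholding remains available via
  `denoise_spec(thresholding = "soft")`.
* **Envelope and arrival picking.**  Envelopes are analytic-signal
  magnitudes (FFT Hilbert transform).  The default time-of-flight picker
  takes the envelope maximum with parabolic sub-sample refinement; a
  threshold-crossing picker is provided because peak picking is not the
  only convention in use.
* **Sound-speed regression.**  Ordinary least squares of distance on
  arrival time; the slope is the speed and the time-axis intercept
  estimates any instrumental delay, which the distance-sweep experiment
  can inject and recover.
* **Frame averaging.**  Non-overlapping blocks of k adjacent frames
  (3000 raw frames at 1 ms intervals with k = 10 give 300 frames at
  10 ms resolution).  Non-overlapping averaging was adopted because the
  3000 → 300 frame accounting only works without overlap; a sliding
  window would yield 2991 frames.  Non-divisible frame counts drop the
  trailing remainder with a warning.

The SNR convention throughout is peak signal amplitude over noise standard
deviation, in dB — the quantity `add_noise()` targets (referenced to the
peak of the noiseless data) and `compute_snr()` measures from disjoint
signal and noise windows.

## Numerical choices

**Field solver.**  Conductivity-weighted 5-point finite differences with
harmonic-mean face conductances (so insulating inclusions need no special
casing), Dirichlet electrode discs, and a grounded outer boundary
(bath much larger than the gap; a circular grounded boundary is available
because the two-cylinder problem then has an exact image-charge solution
to test against).  In the 2p polarity mode the grounded boundary is also
the return path — with both electrodes driven positive the circuit must
close somewhere, and a distant grounded bath is the simplest physically
sensible closure.  The sparse SPD system is solved by a direct Cholesky
factorization (Matrix/CHOLMOD) rather than conjugate gradients: at the
grid sizes used (up to ~10⁵ unknowns) the direct solve is faster and
exact, and the discrete residual is still verified against a 1e-8
relative tolerance with a hard failure if unmet.  The solver's oracle
test uses single-pixel "point" electrodes, whose effective electrostatic
radius under the 5-point Laplacian is the square-lattice Green's-function
constant \(r_0 = h\,e^{-\gamma}/2^{3/2} \approx 0.1985\,h\); with that
radius the analytic two-line-charge (plus image) solution matches the
solve to well under 0.1% in the interior.

**Delta discretization.**  Source pixels deposit into detector time bins
by linear two-sample splitting (nearest-sample binning is available);
back-projection samples \(b(t)\) by linear interpolation.  Central
differences (one-sided at the ends) implement every time derivative.

**The uniform-disc oracle.**  The forward model is validated against the
closed-form shell integral of a uniform disc, whose chord geometry gives
\(p(t) \propto \theta(r)\) with \(\theta\) the half-angle subtended at
the detector.  The derivative of this solution diverges at the two
instants where the integration shell is tangent to the disc edge
(inverse-square-root edges); any discretization disagrees pointwise
there, so the L2 comparison excludes four samples around each tangency
(over 99% of the support is kept) and separately checks the bipolar
zero-crossing timing.  An anti-aliased (area-coverage) rasterization of
the disc is used, which is the consistent discretization of a uniform
source.

**Element directivity and the centre-gain curve.**  With ideal point
detectors, UBP compensates geometric spreading exactly: the reconstructed
peak of a fixed source is essentially independent of its position (flat
to within discretization jitter).  The real-array behaviour — images
brightening as a source approaches the ring centre — is a finite-aperture
effect: a central source is seen broadside by every element, an
off-centre source increasingly obliquely.  `propagate()` therefore offers
an optional narrowband aperture factor
\(\cos\theta\,\mathrm{sinc}(\pi w \sin\theta/\lambda_c)\) (default off,
i.e. ideal points).  `center_gain_curve()` enables it with
\(w = 0.3\ \mathrm{mm} = \lambda_c\) at 5 MHz — the largest width whose
directivity stays null-free and monotone in angle — and samples at
160 MHz so that arrival-phase discretization jitter (~0.1%) stays far
below the per-step directivity gain.

**Round-trip fidelity.**  An in-plane ring paired with the 3-D UBP kernel
is not an exact inverse for sheet sources: reconstructions carry a
negative halo around positive sources.  The round-trip test therefore
correlates the true (non-negative) source with the positive part of the
signed UBP image.

## The synthetic-data generators

The experiment drivers are the package's study conditions, not
illustrations:

* `run_distance_sweep()` — compact source, single detector stepped
  30–55 mm in 5 mm steps, 30 dB noise, band + low-pass filtering,
  envelope-peak arrivals, speed regression.
* `run_voltage_sweep()` — fixed 1p1g pair (3.2 mm gap, so 100–900 V spans
  ≈0.3–2.8 kV/cm nominal), full field solve per voltage, detection at a
  50 mm standoff.  Defaults are noiseless: the sweep characterizes the
  deterministic quadratic law of the model (the bench measurement it
  mirrors used repeated-pulse averaging); noise is available via
  overrides.  The per-pulse energy uses \(V^2\tau_{\mathrm{eff}}/R\) with
  a configurable 50 Ω load — the linearity readout is invariant to the
  load choice.
* `run_video()` — voltage-ramp (static phantom, amplitude ramping
  100→1000 V, channel data scaled per frame by \(V^2\) using the
  linearity of the forward model) and moving-source (fixed-amplitude
  0.4 mm source translated from 40 mm off-centre to the centre) videos:
  fixed-level thermal noise per raw frame, streaming non-overlapping
  k-frame averaging (raw stacks are never materialized), envelope-UBP
  reconstruction per averaged frame, joint normalization.  The moving
  source is 0.4 mm FWHM so its emission lies inside the 2–6 MHz band
  (the imaged electrodes it emulates are 127 µm); its noise level is
  calibrated at the ring centre, the field-of-view reference point, so
  frames with the source closer to the elements exceed the target SNR.
  Desk-scale defaults (64 elements, 500 raw frames, 0.5 mm video pixels)
  keep each scenario under ~30 s; `profile = "full"` switches to
  128 elements and 3000 raw frames.
* `run_phantom()` — static 1p1g / 2p electrode-pair imaging, showing the
  driven-electrode concentration and the mirror symmetry respectively.

What these generators emulate: geometry, pulse scaling, band-limited
N-wave emission, thermal noise, frame timing.  What they do not emulate:
tissue heterogeneity of sound speed or acoustic attenuation, element
bandwidth variation, electronic interference, cavitation or bubble
signals, and conductivity dynamics during pulse trains.  Tests passing on
these phantoms therefore validate the algorithms and their scaling laws,
not performance on real tissue; the instrument-bound figures of merit
(absolute SNR in dB, penetration depth, micrometre-scale resolution) are
covered only qualitatively.

## Problem sizes and runtimes

The shipped tests and the acceptance script use: a 321² grid at 0.25 mm
for the field-solver oracle; a 129² grid for phantom solves; 12.5 µm
pixels for the disc oracle; 128 elements and 0.1 mm pixels for
localization; desk-scale videos as above.  The full test suite runs in
about 90 s on one CPU; the acceptance script in about 35 s.

## Known limitations

* Homogeneous sound speed only; no attenuation, no dispersion.
* 2-D throughout; the thin-slice/3-D-weighting pairing makes UBP
  quantitative only up to the sheet-source halo discussed above.
* The directivity model is narrowband and in-plane; real elements are
  elevation-focused with frequency-dependent apertures.
* The quasi-static solve ignores electrode polarization impedance and
  thermal feedback on conductivity.
* The container import for externally deposited waveform archives is a
  schema adapter stub: the package reads only its own documented layout.
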