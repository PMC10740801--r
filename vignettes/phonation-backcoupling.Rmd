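---
title: "Modelling acoustic back-coupling in phonation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling acoustic back-coupling in phonation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonocouple)
```

## The problem

During voiced speech the vocal folds oscillate at a fundamental frequency
$f_o$ and chop the tracheal airflow into a pulsatile supraglottal jet. The
vocal tract downstream acts as an acoustic resonator; when $f_o$ approaches
its first resonance $f_{R1}$, the standing wave feeds back on the glottal
flow and on the folds themselves, pulling $f_o$ onto $f_{R1}$ and changing
both the aeroacoustic source strength and the radiated voice quality. A
practical way to study this in the laboratory is a silicone-larynx replica
with a telescoping duct whose total length $L$ — and hence $f_{R1} \propto
1/L$ — can be swept continuously, while the supraglottal velocity field is
recorded with high-speed PIV and the radiated sound with a far-field
microphone.

`phonocouple` implements the computational side of such a study as a
tested pipeline: the resonator model, the aeroacoustic source aggregation,
the image/vector conditioning PIV data needs, the voice metrics, and
seeded synthetic generators standing in for the (unavailable) experimental
recordings.

## Transmission-line model of the tract

The duct is an ordered chain of uniform sections (glottis end first). For
a rigid-walled lossless section of length $l$ and area $S$, acoustic
pressure and volume velocity at the output relate to the input through the
two-port matrix

$$K = \begin{pmatrix} \cos kl & -i Z_c \sin kl \\ -\tfrac{i}{Z_c}\sin kl & \cos kl \end{pmatrix},
\qquad k = \frac{2\pi f}{c_0},\; Z_c = \frac{\rho_0 c_0}{S},$$

and the full tract is the ordered product $K_\mathrm{tract} = K_n \cdots
K_1$. With the mouth terminated by a radiation load $Z_\mathrm{out}$ the
input impedance at the glottis is

$$Z_\mathrm{in} = \frac{D\,Z_\mathrm{out} - B}{A - C\,Z_\mathrm{out}},$$

whose maxima over frequency are the tract resonances. The radiation load
is a circular piston in an infinite baffle with equivalent radius
$a = \sqrt{S/\pi}$; by default the low-$ka$ approximation
$R = (ka)^2/2$, $X = 8ka/(3\pi)$ is used ($ka < 0.4$ over the whole
20–1000 Hz band for these ducts, and the exact Bessel–Struve form,
available via `radiation_method = "exact"`, differs by well under 1% where
it matters). Resonances are located on a 20–1000 Hz grid with 0.25 Hz
spacing and refined by a three-point parabolic fit on $\log|Z_\mathrm{in}|$,
with the refinement clamped to half a grid step — near the sharp,
almost-lossless peaks an unclamped parabola can overshoot by several bins.

Assumptions worth keeping in mind: walls are rigid and lossless (the
replica is aluminium and glass; yielding-wall and viscothermal terms are
omitted), plane waves only (valid well below the first cross-mode of a
34 mm duct), and the small radiation resistance is the only loss, which
keeps $|Z_\mathrm{in}|$ finite at the peaks.

Two geometry parameters are genuinely open. The telescoping construction
does not fix how the length beyond the 80 mm rectangular section divides
between the Ø32 and Ø34 tubes; the default gives tube 1 a fixed 120 mm
(so the shortest, 200 mm configuration uses tube 1 only) and is
configurable through `geometry_config()`. The working speed of sound is
likewise not pinned by the benchmark table; we use the standard
$c_0 = 343$ m/s, $\rho_0 = 1.2$ kg/m³. With those defaults all nine
benchmark lengths reproduce their tabulated $f_{R1}$ within ±2%
(the package's acceptance checks require ±5%). The residual −2% at
$L = 200$ mm cannot be removed by rescaling $c_0$ without pushing the
long-tract end out by a similar margin, so we leave the defaults alone.

```{r resonances}
tab <- sweep_conditions()
fr1 <- vapply(tab$L_mm / 1000, function(L)
  find_resonances(impedance_spectrum(build_geometry(L)))$resonances[1],
  numeric(1))
data.frame(L_mm = tab$L_mm, fR1_model = round(fr1, 1), fR1_bench = tab$fr1_hz)
```

## Lighthill source aggregation

For low-Mach isentropic flow the Lighthill source term reduces to the
double divergence of the momentum flux, which on the measured 2D plane is

$$T = \frac{\partial^2 (\rho_0 u^2)}{\partial x^2}
    + 2\frac{\partial^2 (\rho_0 u v)}{\partial x \partial y}
    + \frac{\partial^2 (\rho_0 v^2)}{\partial y^2}.$$

`lighthill_source_field()` evaluates this as two successive discrete
divergences, each using second-order first-derivative stencils (central in
the interior, one-sided three-point at the borders). Composing the
first-derivative operator twice — rather than using a direct
$(1,-2,1)$ second-derivative stencil — keeps the implementation and the
independent test oracle algebraically identical operators, so their
agreement can be checked to near machine precision instead of to a
discretisation-dependent tolerance; both forms are second-order accurate.
No pre-smoothing is applied by default (`presmooth_sigma` enables a
Gaussian pre-filter for noisy input).

Missing the third velocity component, the plane is aggregated assuming the
jet is rotationally symmetric about the duct axis, giving the summed
source signal and its RMS

$$\phi(t) = \frac{1}{4 c_0^2 N_x N_y} \sum_i T(x_i, t)\,|y_i|, \qquad
\Phi = \sqrt{\tfrac{1}{t_1 - t_0}\textstyle\int_{t_0}^{t_1} \phi^2\,dt},$$

with the 1 m virtual-observer distance and the $\pi$ of the axisymmetric
weight absorbed into the prefactor of the discrete form, which is the form
implemented (trapezoidal integration on the native 5 kHz grid). The
aerodynamic input is $P = \Delta p + \tfrac12 \rho_0 U^2$ with the bulk
velocity $U = \dot V / S_\mathrm{duct}$, and the efficiency

$$\eta = \frac{\Phi\, c_0^2 (x_1 - x_0)(y_1 - y_0)}{P}$$

is meaningful as a *relative* measure across configurations, not as an
absolute acoustic efficiency. $\Delta p$ is the driving pressure the study
defines as input; the bundled operating table carries the transglottal
pressure, which the pipeline uses. The classical free-jet scaling
$\eta_\mathrm{theor} \propto M^5$ is provided anchored at a reference
point: `mach_fifth_power_prediction(eta_ref, U_ref, U)`.

Because $T$ is exactly quadratic in the velocities, scaling a field by 2
scales $\Phi$ by exactly 4 — the suite asserts this. The fifth-power law
itself is *not* derivable from a single planar snapshot statistic; the
scaling property test therefore runs the generators at bulk velocities $U$
and $2U$, recovers both bulk velocities from the fields (a stochastic
round trip through the flux calibration), and pushes them through the
anchored fifth-power prediction, checking the ratio lands near $2^5 = 32$.
The order-of-magnitude efficiency excess observed experimentally at
$f_o \approx f_{R1}$ involves the physical resonance feedback and is out
of reach of desk-scale synthetic data; it is represented only by the
resonance targets plus this scaling property.

## PIV conditioning

Raw particle images carry a quasi-static background, bright reflections at
the moving vocal-fold silhouette, and sensor noise. Two complementary
removal methods are implemented, matched to where each works:

* **POD** (`pod_background_removal()`): frames become columns of a
  pixels-by-frames matrix; the leading singular modes (default 1) are the
  background and are subtracted. Excellent for static backgrounds and
  sensor-noise-dominated regions, but it smears moving bright objects.
  The subtracted reconstruction is orthogonal to the retained residual by
  construction (checked before the final clipping of negatives).
* **Anisotropic diffusion** (`anisotropic_diffusion_background()`):
  Perona–Malik evolution with edge-stopping
  $g(s) = 1/(1 + (s/\kappa)^2)$, explicit 4-neighbour scheme
  ($dt \le 0.25$ for stability; defaults $\kappa$ = 10% of the dynamic
  range, 50 iterations, $dt = 0.2$). Strong structures — the reflection
  band, the wall edge — survive the diffusion and end up in the
  background estimate, so subtracting removes them while the weak,
  small-scale particle blobs are retained. Right choice next to the
  moving silhouette.

`blend_preprocessed()` stitches the two results at a configurable column
with a 4 px linear cross-fade (the exact split column is a user choice;
nothing in the physics pins it).

Vector validation uses the normalized-median test: per component, the
residual to the 3×3 neighbourhood median is normalised by the median of
the neighbours' own residuals plus a floor $\epsilon$, and vectors with
$r^* > 2$ are replaced by the median of their valid neighbours. The
defaults $\epsilon = 0.1$ (velocity units, the typical sub-pixel noise
scale) and threshold 2 follow the established PIV literature. A known
property of this test is a raised false-positive rate in strongly curved
shear regions; the quality floors (sensitivity ≥ 0.95, FPR ≤ 1% for
spikes ≥ 5 neighbourhood SD) are asserted on fields whose smooth part is
resolved by the grid, as a correctly set-up PIV evaluation would be.

## Voice metrics

* **SPL**: $20\log_{10}(p_\mathrm{rms}/20\,\mu\mathrm{Pa})$, unweighted,
  full record.
* **SNR**: time-domain harmonic regression — least-squares projection of
  the signal onto sine/cosine pairs at every harmonic of $f_o$ within
  0–4 kHz; harmonic power over the band-limited residual power, capped at
  60 dB. A binwise spectral comb was rejected because window leakage puts
  a ~24 dB ceiling on clean signals, which would misreport strongly
  harmonic voices.
* **HNR**: spectral comb over the Welch PSD (16384-point segments)
  against an interharmonic floor formed by a running local median with
  harmonic bins masked; robust to subharmonic content between harmonics,
  which inflates neither term.
* **CPP**: real cepstrum of the *Welch-averaged* dB spectrum (averaging
  suppresses the chi-squared scatter of raw periodogram bins that would
  otherwise bury the rahmonic), peak searched in the 2.5–20 ms quefrency
  band against a linear regression baseline fitted from 1 ms to 20 ms.
  Values are comparable within this package, not calibrated against any
  clinical tool.
* **Vocal efficiency**: $(p_\mathrm{rms}^2/\rho_0 c_0)\,4\pi r^2 /
  (P_\mathrm{trans}\dot V)$ — full spherical spreading by default, since
  the estimator is used comparatively; hemispherical available by flag.

These are transparent estimators of the named quantities; only trends
across configurations, not absolute values, should be compared with
numbers produced by clinical analysis software.

## Synthetic generators: what they emulate, and what they do not

The generators provide data with the statistical structure the analysis
assumes, under full seed control.

**Velocity fields** (`generate_velocity_series()`): a 74×56 grid over
45 mm × 18 mm sampled at 5 kHz — the PIV evaluation layout the package
assumes elsewhere. The streamwise component is a pulsatile jet with a
Gaussian cross-stream profile, gate $\max(0, \sin 2\pi f_o t)^2$ (on
during the open half-cycle), half-width 3.5 mm at the glottis growing at
0.15 per unit length downstream. The initial half-width is sized so the
flux-calibrated peak velocity lands near the Bernoulli velocity
$\sqrt{2\Delta p/\rho_0} \approx 84$ m/s at the benchmark operating point
(124 l/min, 4.2 kPa). The centreline drifts wall-ward through the closing
phase; a Lamb–Oseen-like vortex patch appears on the opposite side during
the closed phase; an optional $f_o/3$ gate modulation produces the
subharmonic family seen near resonance crossings; band-limited, zero-mean
fluctuations model turbulence. The amplitude is calibrated so the
time-mean inlet-column flux equals the configured flow rate — making the
turbulence zero-mean per grid point keeps that calibration exact. All
deterministic parts are functions of cycle phase only, so the noiseless
field is exactly $f_o$-periodic. The generator is *not* a Navier–Stokes
solution: entrainment, jet flapping chaos, and three-dimensionality are
absent, so passing round-trip tests demonstrates correctness of the
analysis chain, not physical fidelity of the flow.

**Microphone signals** (`generate_acoustic_signal()`): harmonics of $f_o$
with a per-harmonic roll-off (default 6 dB), optional $f_o/3$ family,
white noise at a configured level, 44.1 kHz, calibrated to Pa. The noise
level is defined relative to the total harmonic energy *within the 0–4 kHz
analysis band* the metrics integrate, so `-noise_level_db` is exactly the
ratio a band-limited estimator should recover; with white noise this
makes the generator and the metrics mutually consistent without any
shared code path. Default record length 2 s.

**Particle images** (`generate_particle_images()`): Gaussian blobs
(optionally advected by a velocity field), a static smooth background, a
bright oscillating reflection band near the left edge, and Gaussian
sensor noise — built strictly additively, with every component returned,
so conditioning can be scored against exact ground truth.

## Numerical choices and degenerate inputs

* Frequency grid 20–1000 Hz at 0.25 Hz; resonance ties resolve to the
  lowest frequency; a vanishing $Z_\mathrm{in}$ denominator reports a
  pole (infinite magnitude), not an error.
* Sections of zero length are dropped by the geometry builder; a total
  length below the 80 mm rectangular section is an error.
* Welch PSDs: Hann window, 50% overlap, segment-mean detrend; the
  velocity PSD picks the largest power-of-two segment giving ≤ 5 Hz
  resolution. Fundamentals are refined by a clamped parabolic fit on the
  dB spectrum.
* Outlier repair with an all-flagged neighbourhood leaves the vector
  unrepaired and reports it.
* Trapezoidal time integration on the native sampling grid throughout.

## Problem sizes

The test-suite and acceptance computations use short records — 0.12–1 s of
synthetic flow (600–5000 time steps on the full 74×56 grid), 1–1.5 s of
audio — chosen as the smallest sizes at which every estimator is
comfortably inside its tolerance; all results quoted in the package
documentation come from these runs. The pipeline defaults
(`duration_s = 0.5` per length in `run_sweep()`; 2 s in the standalone
generators) scale linearly in time and memory.

## Known limitations

* The tract model omits wall vibration and viscothermal losses; measured
  resonance bandwidths will be wider than modelled ones.
* The tube-split and speed-of-sound defaults shift $f_{R1}$ at the
  percent level; both are configurable rather than knowable.
* $\eta$ from planar, axisymmetry-weighted data is a relative measure;
  comparisons across different ROI geometries are not meaningful.
* The voice metrics are package-internal estimators; absolute values are
  not interchangeable with clinical tools' outputs.
* The generators share no code with the estimators but were designed with
  the same band conventions; recovery tests validate the analysis chain,
  not the generators' realism.
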