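# phonocouple

Tools for studying **acoustic back-coupling in phonation**: the
interaction between the vocal-fold oscillation frequency `f_o` and the
first acoustic resonance `f_R1` of the vocal tract. When the two
frequencies approach each other, the standing wave in the tract feeds
back on the glottal jet and on the folds, pulling `f_o` onto `f_R1` and
changing both the aeroacoustic source strength and the radiated voice
quality. The package is written for researchers who study this effect on
length-variable synthetic larynx rigs with high-speed PIV and far-field
microphones, and for anyone who needs a tested, scriptable version of the
standard computations involved.

It implements:

* **Transmission-line tract model** — per-section chain matrices
  `K = [[cos kl, -iZc sin kl], [-i sin kl / Zc, cos kl]]` chained from
  glottis to mouth, a piston-in-an-infinite-baffle radiation load, the
  input impedance `Zin = (D Zout - B) / (A - C Zout)`, resonance
  extraction from the maxima of `|Zin|`, and length sweeps
  (`build_geometry()`, `impedance_spectrum()`, `find_resonances()`,
  `impedance_map()`).
* **Lighthill source aggregation on planar velocity fields** —
  `T = div(div(rho0 u u))` by second-order finite differences, the
  axisymmetry-weighted summed source
  `phi(t) = 1/(4 c0^2 Nx Ny) * sum_i T(x_i, t) |y_i|`, its RMS `Phi`, the
  aerodynamic input `P = dp + rho0 U^2 / 2`, the relative efficiency
  `eta = Phi c0^2 (x1-x0)(y1-y0) / P`, and the anchored fifth-power
  Mach-number prediction (`lighthill_source_field()`,
  `summed_source_signal()`, `aeroacoustic_efficiency()`, ...).
* **PIV conditioning** — POD background removal, Perona–Malik
  anisotropic-diffusion background removal for moving-silhouette regions,
  region blending, and normalized-median (universal) outlier detection
  with neighbour-median repair.
* **Voice metrics** — SPL, SNR (harmonic regression), HNR (spectral comb
  over an interharmonic median floor), cepstral peak prominence, vocal
  efficiency.
* **Seeded synthetic generators** for velocity-field series (pulsatile
  deflecting glottal jet with supraglottal vortex and turbulence on a
  74×56 grid at 5 kHz), microphone-like harmonic signals at 44.1 kHz, and
  particle-image stacks with exact ground truth — so the whole pipeline
  is testable without experimental recordings.
* **A sweep driver** (`load_run_config()`, `run_sweep()`,
  `export_report()`) reproducing the length-sweep workflow end to end,
  seeded from a bundled table of benchmark operating points
  (`sweep_conditions()`).

## Worked example

Build the 400 mm tract, inspect its resonances, then run a three-length
sweep on synthetic data:

```r
library(phonocouple)

g <- build_geometry(0.400)
g
#> Tract geometry: 3 section(s), total length 400.0 mm
#> Tube section [supraglottal duct]: rectangular, length 80.0 mm, area 270.0 mm^2
#> Tube section [tube 1]: circular, length 120.0 mm, area 804.2 mm^2
#> Tube section [tube 2]: circular, length 200.0 mm, area 907.9 mm^2

find_resonances(impedance_spectrum(g))
#> Resonances (Hz): 245.4, 683.1

cfg <- load_run_config(list(lengths_mm = c(200, 400, 700), seed = 1,
                            duration_s = 0.4))
rep <- run_sweep(cfg, keep_details = FALSE)
rep$summary[, c("L_mm", "fR1_Hz", "fo_Hz", "fo_extracted_Hz", "Phi",
                "eta", "eta_theor")]
#>   L_mm fR1_Hz fo_Hz fo_extracted_Hz     Phi      eta eta_theor
#> 1  200  516.6 151.3           151.3 0.27187 0.006106 0.0061058
#> 2  400  245.4 225.7           225.8 0.20406 0.005094 0.0029212
#> 3  700  132.7 136.8           136.8 0.05371 0.002020 0.0001048
```

Reading the output: `fR1_Hz` is the first input-impedance maximum of each
tract — it falls as the duct lengthens, crossing the vocal-fold frequency
range near 600–700 mm. `fo_extracted_Hz` confirms the analysis chain
recovers each configured fundamental from the synthetic velocity fields
(225.7 Hz is the frequency-jump case where `f_o` locks near `f_R1`).
`Phi` (RMS aggregated Lighthill source) and `eta` (relative aeroacoustic
efficiency) fall with length as the driving flow rate drops, while
`eta_theor` is the fifth-power Mach-number prediction anchored at the
shortest tract; the growing gap between `eta` and `eta_theor` at long
tracts is the signature quantity the sweep is designed to expose. The
full summary also carries SPL, SNR, HNR, CPP and vocal efficiency from
the synthetic microphone channel.

`vignettes/phonation-backcoupling.Rmd` documents the model assumptions,
estimator definitions, generator design and numerical choices.

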