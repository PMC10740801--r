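Package: phonocouple
Title: Vocal-Tract Acoustics, Aeroacoustic Sources and Voice Metrics for
    Phonation Back-Coupling Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying acoustic back-coupling between the vocal
    tract and the glottal source in phonation experiments with
    length-variable vocal tracts. Implements a transmission-line model of
    a segmented vocal tract (chain matrices, piston-in-baffle radiation
    load, input impedance and resonance extraction), aggregation of the
    Lighthill aeroacoustic source term on time-resolved planar velocity
    fields with an axisymmetry weighting, PIV image conditioning (POD and
    anisotropic-diffusion background removal, normalized-median outlier
    validation), acoustic voice-quality metrics (SPL, SNR, HNR, cepstral
    peak prominence, vocal efficiency), and seeded synthetic generators
    for velocity-field series, microphone-like signals and particle-image
    stacks so every stage can be exercised without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
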