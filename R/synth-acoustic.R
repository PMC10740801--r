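#' Configuration for the synthetic microphone-signal generator
#'
#' @param fo Fundamental frequency, Hz.
#' @param n_harmonics Number of harmonics of `fo` to synthesise.
#' @param harmonic_rolloff_db Amplitude roll-off per harmonic step, dB; the
#'   k-th harmonic has amplitude `10^(-(k - 1) rolloff / 20)` relative to
#'   the first.
#' @param noise_level_db Noise energy relative to the total harmonic energy,
#'   dB, measured within the voice analysis band (`noise_band`); `-Inf`
#'   disables noise. With white noise the in-band energy is the stated
#'   fraction of the harmonic energy, so `-noise_level_db` is the
#'   harmonic-to-noise ratio a band-limited estimator should recover.
#' @param subharmonic_fraction Amplitude ratio of the `fo/3` family relative
#'   to the harmonic roll-off envelope at the same frequency, in [0, 1].
#' @param duration Record length, s.
#' @param sample_rate Sampling rate, Hz. Default 44100. Must exceed
#'   `2 fo n_harmonics` (no aliased harmonics).
#' @param calibration Pa per signal unit. The returned samples are already
#'   calibrated to Pa.
#' @param noise_band Analysis band for the noise calibration, Hz.
#' @param seed Integer seed.
#'
#' @return An `acoustic_config` list.
#' @export
acoustic_config <- function(fo = 150, n_harmonics = 20L,
                            harmonic_rolloff_db = 6, noise_level_db = -20,
                            subharmonic_fraction = 0, duration = 2,
                            sample_rate = 44100, calibration = 1,
                            noise_band = c(0, 4000), seed = 1L) {
  cfg <- list(fo = fo, n_harmonics = as.integer(n_harmonics),
              harmonic_rolloff_db = harmonic_rolloff_db,
              noise_level_db = noise_level_db,
              subharmonic_fraction = subharmonic_fraction,
              duration = duration, sample_rate = sample_rate,
              calibration = calibration, noise_band = noise_band,
              seed = as.integer(seed))
  if (cfg$fo <= 0 || cfg$duration <= 0 || cfg$sample_rate <= 0 ||
      cfg$calibration <= 0)
    stop("acoustic config: fo, duration, sample_rate, calibration must be positive",
         call. = FALSE)
  if (cfg$n_harmonics < 1L)
    stop("acoustic config: need at least one harmonic", call. = FALSE)
  if (cfg$sample_rate <= 2 * cfg$fo * cfg$n_harmonics)
    stop("acoustic config: sample_rate must exceed 2 * fo * n_harmonics (aliasing)",
         call. = FALSE)
  if (cfg$subharmonic_fraction < 0 || cfg$subharmonic_fraction > 1)
    stop("acoustic config: subharmonic_fraction must be in [0, 1]", call. = FALSE)
  structure(cfg, class = "acoustic_config")
}

#' Calibrated acoustic pressure signal
#'
#' Container for a uniformly sampled sound-pressure series in Pa.
#'
#' @param samples Numeric vector of pressure samples, Pa.
#' @param sample_rate Sampling rate, Hz.
#' @param calibration Pa per raw unit used when the samples were converted
#'   (kept for provenance; `samples` are already in Pa).
#' @return An `acoustic_signal`.
#' @export
acoustic_signal <- function(samples, sample_rate, calibration = 1) {
  if (!is.numeric(samples) || !length(samples))
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 calibration = calibration),
            class = "acoustic_signal")
}

#' @export
print.acoustic_signal <- function(x, ...) {
  cat(sprintf("Acoustic signal: %.3f s @ %g Hz, rms %.4g Pa\n",
              length(x$samples) / x$sample_rate, x$sample_rate,
              sqrt(mean(x$samples^2))))
  invisible(x)
}

#' Generate a synthetic microphone-like voice signal
#'
#' Sum of harmonics of `fo` with a fixed per-harmonic roll-off, an optional
#' subharmonic family at `m fo / 3` (m not divisible by 3) scaled by
#' `subharmonic_fraction`, and seeded white noise calibrated so its energy
#' inside `noise_band` sits `noise_level_db` below the total harmonic
#' energy.
#'
#' @param cfg An [acoustic_config()].
#' @return An [acoustic_signal()] in Pa.
#' @examples
#' s <- generate_acoustic_signal(acoustic_config(duration = 0.2))
#' spl(s)
#' @export
generate_acoustic_signal <- function(cfg) {
  if (!inherits(cfg, "acoustic_config"))
    stop("`cfg` must be an `acoustic_config`", call. = FALSE)
  n <- round(cfg$duration * cfg$sample_rate)
  t <- (seq_len(n) - 1L) / cfg$sample_rate
  nyq <- cfg$sample_rate / 2

  amps <- 10^(-(seq_len(cfg$n_harmonics) - 1L) * cfg$harmonic_rolloff_db / 20)
  s <- rep(0, n)
  for (k in seq_len(cfg$n_harmonics))
    s <- s + amps[k] * sin(2 * pi * k * cfg$fo * t)
  harm_power <- sum(amps^2) / 2

  if (cfg$subharmonic_fraction > 0) {
    env <- function(f) 10^(-(f / cfg$fo - 1) * cfg$harmonic_rolloff_db / 20)
    for (m in seq_len(3L * cfg$n_harmonics)) {
      if (m %% 3L == 0L) next
      fm <- m * cfg$fo / 3
      if (fm >= nyq) break
      s <- s + cfg$subharmonic_fraction * env(fm) * sin(2 * pi * fm * t)
    }
  }

  if (is.finite(cfg$noise_level_db)) {
    bw <- diff(cfg$noise_band)
    if (bw <= 0 || cfg$noise_band[2] > nyq)
      stop("acoustic config: noise_band must be increasing and below Nyquist",
           call. = FALSE)
    # white noise: in-band energy fraction is bw / nyquist
    sigma <- sqrt(harm_power * 10^(cfg$noise_level_db / 10) * nyq / bw)
    set.seed(cfg$seed)
    s <- s + sigma * stats::rnorm(n)
  }

  acoustic_signal(cfg$calibration * s, cfg$sample_rate, cfg$calibration)
}
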