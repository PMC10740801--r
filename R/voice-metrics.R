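hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))

# Welch power spectral density, averaged over the columns of a matrix
# (time along rows). One-sided, segment-mean detrended, Hann windowed.
# Vectorised across columns via mvfft so that averaging over thousands of
# grid points stays cheap.
welch_psd <- function(X, fs, nperseg, overlap = 0.5) {
  if (is.vector(X)) X <- matrix(X, ncol = 1L)
  nt <- nrow(X)
  nperseg <- min(nperseg, nt)
  step <- max(1L, round(nperseg * (1 - overlap)))
  starts <- seq(1L, nt - nperseg + 1L, by = step)
  w <- hann_window(nperseg)
  norm <- fs * sum(w^2)
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- X[s:(s + nperseg - 1L), , drop = FALSE]
    seg <- sweep(seg, 2L, colMeans(seg))
    F <- stats::mvfft(seg * w)
    P <- rowMeans(Mod(F[seq_len(nf), , drop = FALSE])^2) / norm
    acc <- acc + P
  }
  psd <- acc / length(starts)
  psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]   # one-sided (not DC / Nyquist)
  list(frequencies = (seq_len(nf) - 1L) * fs / nperseg, psd = psd,
       resolution = fs / nperseg)
}

new_spectrum <- function(frequencies, psd, resolution) {
  structure(list(frequencies = frequencies, psd = psd, resolution = resolution),
            class = "spectrum_psd")
}

#' @export
print.spectrum_psd <- function(x, ...) {
  cat(sprintf("PSD spectrum: %d bins, 0-%g Hz, resolution %.3g Hz\n",
              length(x$frequencies), max(x$frequencies), x$resolution))
  invisible(x)
}

#' Domain-averaged velocity power spectral density
#'
#' Welch PSD of the velocity magnitude `|u| = sqrt(u^2 + v^2)` computed per
#' grid point and averaged over all grid points of the field.
#'
#' @param field A `velocity_field_series`.
#' @param seg_len Welch segment length in samples; the default picks the
#'   largest power of two giving at most 5 Hz resolution (and at most the
#'   record length).
#' @param overlap Segment overlap fraction (default 0.5).
#' @return A `spectrum_psd`: list with `frequencies` (Hz), `psd`
#'   ((m/s)^2 / Hz) and `resolution` (Hz).
#' @export
averaged_velocity_psd <- function(field, seg_len = NULL, overlap = 0.5) {
  stopifnot(inherits(field, "velocity_field_series"))
  fs <- field$sample_rate
  nt <- length(field$t)
  if (is.null(seg_len)) {
    seg_len <- 2^ceiling(log2(fs / 5))
    seg_len <- min(seg_len, 2^floor(log2(nt)))
  }
  if (seg_len > nt) stop("segment longer than the record", call. = FALSE)
  mag <- sqrt(field$u^2 + field$v^2)
  X <- matrix(mag, nt, length(field$y) * length(field$x))
  out <- welch_psd(X, fs, seg_len, overlap)
  new_spectrum(out$frequencies, out$psd, out$resolution)
}

parabolic_peak <- function(f, ydb, i) {
  n <- length(ydb)
  if (i <= 1L || i >= n) return(f[i])
  y0 <- ydb[i - 1L]; y1 <- ydb[i]; y2 <- ydb[i + 1L]
  den <- y0 - 2 * y1 + y2
  d <- if (den == 0) 0 else 0.5 * (y0 - y2) / den
  f[i] + max(-0.5, min(0.5, d)) * (f[i + 1L] - f[i])
}

#' Fundamental frequency from a PSD spectrum
#'
#' Frequency of the largest PSD value inside the search band, refined by a
#' three-point parabolic fit on the dB spectrum.
#'
#' @param spec A `spectrum_psd`.
#' @param band_lo,band_hi Search band in Hz (default 50-400 Hz).
#' @return The fundamental frequency in Hz.
#' @export
extract_fundamental <- function(spec, band_lo = 50, band_hi = 400) {
  stopifnot(inherits(spec, "spectrum_psd"))
  sel <- which(spec$frequencies >= band_lo & spec$frequencies <= band_hi)
  if (!length(sel)) stop("empty search band", call. = FALSE)
  ydb <- 10 * log10(pmax(spec$psd, .Machine$double.xmin))
  i <- sel[which.max(spec$psd[sel])]
  parabolic_peak(spec$frequencies, ydb, i)
}

#' Detect subharmonic peaks at thirds of the fundamental
#'
#' Looks for spectral peaks at `m fo / 3` for `m` not divisible by 3. A
#' candidate is reported when the PSD maximum within one bin of the
#' expected frequency exceeds the local median noise floor (computed over
#' roughly +-15 bins, excluding the 5 bins centred on the candidate) by at
#' least `prominence_db`.
#'
#' @param spec A `spectrum_psd`.
#' @param fo Fundamental frequency in Hz (e.g. from
#'   [extract_fundamental()]).
#' @param prominence_db Detection threshold above the local floor, dB
#'   (default 6).
#' @param max_m Highest multiple of `fo/3` to test.
#' @return A `spectral_peaks`: list with `fo`, `harmonics` (matrix of
#'   frequency and dB level for `k fo` in band) and `subharmonics`
#'   (matrix of frequency, dB level and prominence for detected
#'   `m fo / 3`).
#' @export
detect_subharmonics <- function(spec, fo, prominence_db = 6, max_m = 8L) {
  stopifnot(inherits(spec, "spectrum_psd"))
  f <- spec$frequencies
  if (fo <= min(f) || fo >= max(f))
    stop("`fo` must lie inside the spectrum", call. = FALSE)
  ydb <- 10 * log10(pmax(spec$psd, .Machine$double.xmin))
  n <- length(f)
  peak_at <- function(ft) {
    i <- which.min(abs(f - ft))
    ii <- max(1L, i - 1L):min(n, i + 1L)
    j <- ii[which.max(ydb[ii])]
    floor_ii <- setdiff(max(1L, i - 15L):min(n, i + 15L),
                        max(1L, i - 2L):min(n, i + 2L))
    c(freq = f[j], level = ydb[j],
      prom = ydb[j] - stats::median(ydb[floor_ii]))
  }
  harm <- t(vapply(seq_len(max(1L, floor(max(f) / fo))), function(k) {
    p <- peak_at(k * fo); c(p["freq"], p["level"])
  }, numeric(2)))
  colnames(harm) <- c("freq", "level")
  sub <- NULL
  for (m in seq_len(max_m)) {
    if (m %% 3L == 0L) next
    ft <- m * fo / 3
    if (ft <= min(f) + spec$resolution || ft >= max(f)) next
    p <- peak_at(ft)
    if (is.finite(p["prom"]) && p["prom"] > prominence_db)
      sub <- rbind(sub, p)
  }
  if (!is.null(sub)) rownames(sub) <- NULL
  structure(list(fo = fo, harmonics = harm,
                 subharmonics = if (is.null(sub)) matrix(numeric(0), 0, 3,
                                                         dimnames = list(NULL, c("freq", "level", "prom")))
                 else sub),
            class = "spectral_peaks")
}

#' @export
print.spectral_peaks <- function(x, ...) {
  cat(sprintf("Spectral peaks: fo = %.1f Hz, %d harmonics, %d subharmonics\n",
              x$fo, nrow(x$harmonics), nrow(x$subharmonics)))
  invisible(x)
}

#' Sound pressure level
#'
#' `SPL = 20 log10(p_rms / 20e-6)` of a calibrated pressure signal,
#' unweighted, over the full record.
#'
#' @param sig An [acoustic_signal()] in Pa.
#' @return SPL in dB re 20 uPa.
#' @examples
#' spl(acoustic_signal(rep(c(1, -1), 100), 44100)) # p_rms = 1 Pa: 93.98 dB
#' @export
spl <- function(sig) {
  stopifnot(inherits(sig, "acoustic_signal"))
  if (!length(sig$samples)) stop("zero-length signal", call. = FALSE)
  20 * log10(sqrt(mean(sig$samples^2)) / 20e-6)
}

#' Harmonic-comb SNR and HNR estimates
#'
#' Transparent estimators of the signal-to-noise and harmonics-to-noise
#' ratio over a 0-4 kHz analysis band.
#'
#' SNR is computed by harmonic regression in the time domain: the signal is
#' least-squares projected onto sine/cosine pairs at every multiple of `fo`
#' inside the band, the harmonic energy is the power of that projection,
#' and the noise energy is the power of the regression residual band-limited
#' to the analysis band (so it compares against the same bandwidth the
#' harmonics occupy). This avoids the spectral-leakage floor a binwise
#' comb estimator has: for a noiseless harmonic signal the residual is at
#' rounding level and the estimate caps.
#'
#' HNR is spectral: harmonic energy is integrated from the Welch PSD around
#' each harmonic, and the noise term integrates the interharmonic floor (a
#' running local median of the PSD with harmonic bins masked), which makes
#' it robust to subharmonic content sitting between the harmonics.
#'
#' Both ratios are reported in dB and capped at +60 dB.
#'
#' @param sig An [acoustic_signal()].
#' @param fo Fundamental frequency, Hz; extracted from the signal spectrum
#'   (50-400 Hz band) when omitted.
#' @param band_hi Upper edge of the analysis band, Hz (default 4000).
#' @param nperseg Welch segment length for the HNR floor (default 16384,
#'   about 2.7 Hz resolution at 44.1 kHz).
#' @return A list with `snr_db`, `hnr_db` and the `fo` used.
#' @export
snr_hnr <- function(sig, fo = NULL, band_hi = 4000, nperseg = 16384L) {
  stopifnot(inherits(sig, "acoustic_signal"))
  fs <- sig$sample_rate
  n <- length(sig$samples)
  out <- welch_psd(sig$samples, fs, min(nperseg, n))
  f <- out$frequencies; psd <- out$psd; df <- out$resolution
  if (is.null(fo)) {
    sp <- new_spectrum(f, psd, df)
    fo <- extract_fundamental(sp)
  }
  if (fo <= 0 || fo >= band_hi)
    stop("`fo` must lie inside the analysis band", call. = FALSE)
  cap <- function(x) min(x, 60)

  # --- SNR: harmonic regression ------------------------------------------
  t <- (seq_len(n) - 1L) / fs
  ks <- seq_len(floor(band_hi / fo))
  X <- matrix(0, n, 2L * length(ks))
  for (j in seq_along(ks)) {
    X[, 2L * j - 1L] <- sin(2 * pi * ks[j] * fo * t)
    X[, 2L * j] <- cos(2 * pi * ks[j] * fo * t)
  }
  fit <- stats::lm.fit(cbind(1, X), sig$samples)
  harm_part <- sig$samples - fit$residuals - fit$coefficients[1L]
  e_harm_t <- mean(harm_part^2)
  # residual noise restricted to the analysis band
  R <- stats::fft(fit$residuals)
  fr <- (seq_len(n) - 1L) * fs / n
  keep <- fr <= band_hi | fr >= fs - band_hi   # two-sided mask
  e_noise_t <- sum(Mod(R[keep])^2) / n^2
  snr_db <- if (e_noise_t <= e_harm_t * 1e-12) 60 else
    cap(10 * log10(e_harm_t / e_noise_t))

  # --- HNR: spectral comb against the interharmonic median floor ---------
  band <- which(f > 0 & f <= band_hi)
  harm_idx <- integer(0)
  mask <- rep(FALSE, length(f))
  for (k in ks) {
    i <- which.min(abs(f - k * fo))
    harm_idx <- c(harm_idx, (i - 1L):(i + 1L))
    mask[max(1L, i - 2L):min(length(f), i + 2L)] <- TRUE
  }
  harm_idx <- intersect(unique(harm_idx), band)
  e_harm <- sum(psd[harm_idx]) * df
  floor_psd <- vapply(band, function(i) {
    ii <- max(1L, i - 25L):min(length(f), i + 25L)
    ii <- ii[!mask[ii]]
    if (!length(ii)) return(NA_real_)
    stats::median(psd[ii])
  }, numeric(1))
  e_floor <- sum(floor_psd, na.rm = TRUE) * df
  hnr_db <- if (e_floor <= e_harm * 1e-12) 60 else
    cap(10 * log10(e_harm / e_floor))
  list(snr_db = snr_db, hnr_db = hnr_db, fo = fo)
}

#' Cepstral peak prominence
#'
#' Real cepstrum of the Welch-averaged dB power spectrum (the averaging
#' suppresses the chi-squared scatter of raw periodogram bins, which would
#' otherwise bury the rahmonic peak). The cepstral peak is searched in the
#' quefrency band corresponding to 50-400 Hz; a linear regression of
#' cepstrum against quefrency over `[1 ms, quefrency_hi]` provides the
#' baseline, and CPP is the peak height above the regression line at the
#' peak quefrency, in dB.
#'
#' @param sig An [acoustic_signal()]; the record must cover at least 4
#'   periods of the lowest expected fundamental (50 Hz).
#' @param quefrency_lo,quefrency_hi Peak search band in seconds (defaults
#'   1/400 and 1/50 s).
#' @param nperseg Welch segment length for the spectrum (default 4096).
#' @return A list with `cpp_db`, `peak_quefrency` (s) and the implied
#'   `fo` (Hz).
#' @export
cpp <- function(sig, quefrency_lo = 1 / 400, quefrency_hi = 1 / 50,
                nperseg = 4096L) {
  stopifnot(inherits(sig, "acoustic_signal"))
  fs <- sig$sample_rate
  n <- length(sig$samples)
  if (n < 4 * fs / 50) stop("record too short for cepstral analysis", call. = FALSE)
  out <- welch_psd(sig$samples, fs, min(nperseg, 2^floor(log2(n))))
  sdb <- 10 * log10(pmax(out$psd, .Machine$double.xmin))
  m <- length(sdb)
  ext <- c(sdb, rev(sdb[2:(m - 1L)]))     # even extension -> real cepstrum
  ceps <- Re(stats::fft(ext, inverse = TRUE)) / length(ext)
  q <- (seq_along(ext) - 1L) / fs
  fit_sel <- which(q >= 1e-3 & q <= quefrency_hi)
  fit <- stats::lm.fit(cbind(1, q[fit_sel]), ceps[fit_sel])
  peak_sel <- which(q >= quefrency_lo & q <= quefrency_hi)
  if (!length(peak_sel) || !length(fit_sel))
    stop("record too short for the requested quefrency band", call. = FALSE)
  i <- peak_sel[which.max(ceps[peak_sel])]
  baseline <- fit$coefficients[1L] + fit$coefficients[2L] * q[i]
  list(cpp_db = ceps[i] - baseline, peak_quefrency = q[i], fo = 1 / q[i])
}

#' Vocal efficiency
#'
#' Radiated acoustic power over aerodynamic power:
#' `VE = (p_rms^2 / (rho0 c0)) * spreading_area / (Ptrans * flow_rate)`,
#' with spherical spreading (`4 pi r^2`, default) or hemispherical
#' spreading (`2 pi r^2`) from the measurement distance `r`.
#'
#' @param p_rms RMS sound pressure at the microphone, Pa.
#' @param r Microphone distance, m.
#' @param Ptrans Transglottal (driving) pressure, Pa.
#' @param flow_rate Mean glottal volume flow, m^3/s.
#' @param consts [acoustic_constants()].
#' @param spreading `"sphere"` (default) or `"hemisphere"`.
#' @return The dimensionless vocal efficiency.
#' @export
vocal_efficiency <- function(p_rms, r, Ptrans, flow_rate,
                             consts = acoustic_constants(),
                             spreading = c("sphere", "hemisphere")) {
  consts <- as_constants(consts)
  spreading <- match.arg(spreading)
  if (Ptrans <= 0 || flow_rate <= 0)
    stop("aerodynamic power must be positive", call. = FALSE)
  if (p_rms < 0 || r <= 0)
    stop("`p_rms` must be >= 0 and `r` > 0", call. = FALSE)
  area <- if (spreading == "sphere") 4 * pi * r^2 else 2 * pi * r^2
  (p_rms^2 / (consts$rho0 * consts$c0)) * area / (Ptrans * flow_rate)
}
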