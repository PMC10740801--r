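#' Configuration for the synthetic glottal-jet velocity generator
#'
#' Parameters of a seeded generator that emulates time-resolved planar PIV
#' of the supraglottal flow: a pulsatile jet at the fundamental frequency
#' `fo`, wall-ward deflection during the closing phase, a counter-rotating
#' supraglottal vortex in the closed phase, and band-limited turbulent
#' fluctuations. The default grid (74 x 56 vectors over 45 mm x 18 mm at
#' 5 kHz) matches the PIV evaluation settings the package assumes elsewhere.
#'
#' @param fo Fundamental (vocal-fold oscillation) frequency, Hz.
#' @param mean_flow_rate Time-mean glottal volume flow, m^3/s. The generated
#'   field is calibrated so the time-mean volume flux through the inlet
#'   column equals this value.
#' @param duct_area Duct cross-sectional area, m^2 (default 2.7e-4, an
#'   18 mm x 15 mm duct).
#' @param jet_peak_velocity Pre-calibration shape amplitude of the jet, m/s.
#'   After flux calibration the actual peak velocity is set by
#'   `mean_flow_rate`; this parameter only shapes intermediate amplitudes.
#' @param deflection_angle Signed wall-ward jet deflection angle, degrees.
#'   Positive deflects towards positive y (the "top" wall).
#' @param turbulence_level Fluctuation amplitude as a fraction of the
#'   calibrated peak jet velocity. 0 gives a noiseless, exactly fo-periodic
#'   field.
#' @param subharmonic_fraction Amplitude of an fo/3 modulation of the jet
#'   gate, in [0, 1]. 0 disables the subharmonic family.
#' @param duration Record length, s. Default 2.
#' @param sample_rate Sampling rate, Hz. Default 5000.
#' @param nx,ny Grid vector counts in x (streamwise) and y (cross-stream).
#' @param domain_width,domain_height Physical extent of the region of
#'   interest, m (x spans `[0, domain_width]`, y is centred on the duct
#'   axis).
#' @param vortex_strength Circulation scale of the closed-phase vortex as a
#'   fraction of the jet amplitude.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   seed.
#'
#' @return A `flow_config` list.
#' @export
flow_config <- function(fo = 150, mean_flow_rate = 2.0e-3,
                        duct_area = 2.7e-4, jet_peak_velocity = 40,
                        deflection_angle = 12, turbulence_level = 0.05,
                        subharmonic_fraction = 0, duration = 2,
                        sample_rate = 5000, nx = 74, ny = 56,
                        domain_width = 0.045, domain_height = 0.018,
                        vortex_strength = 0.25, seed = 1L) {
  cfg <- list(fo = fo, mean_flow_rate = mean_flow_rate, duct_area = duct_area,
              jet_peak_velocity = jet_peak_velocity,
              deflection_angle = deflection_angle,
              turbulence_level = turbulence_level,
              subharmonic_fraction = subharmonic_fraction,
              duration = duration, sample_rate = sample_rate,
              nx = as.integer(nx), ny = as.integer(ny),
              domain_width = domain_width, domain_height = domain_height,
              vortex_strength = vortex_strength, seed = as.integer(seed))
  if (cfg$fo <= 0 || cfg$mean_flow_rate <= 0 || cfg$sample_rate <= 0 ||
      cfg$duration <= 0)
    stop("flow config: fo, mean_flow_rate, duration, sample_rate must be positive",
         call. = FALSE)
  if (cfg$turbulence_level < 0)
    stop("flow config: turbulence_level must be >= 0", call. = FALSE)
  if (cfg$subharmonic_fraction < 0 || cfg$subharmonic_fraction > 1)
    stop("flow config: subharmonic_fraction must be in [0, 1]", call. = FALSE)
  if (cfg$duration * cfg$sample_rate < 2 * cfg$sample_rate / cfg$fo)
    stop("flow config: record must cover at least 2 periods of fo", call. = FALSE)
  if (cfg$nx < 3L || cfg$ny < 3L)
    stop("flow config: grid must be at least 3 x 3", call. = FALSE)
  structure(cfg, class = "flow_config")
}

#' Generate a synthetic glottal-jet velocity-field series
#'
#' Deterministic (seeded) emulation of supraglottal PIV data. The
#' streamwise component is a pulsatile jet with a Gaussian cross-stream
#' profile whose half-width grows downstream; its gate follows
#' `max(0, sin(2 pi fo t))^2` so the jet switches on and off with the
#' glottal cycle. During the closing phase the jet centreline drifts
#' towards the configured wall; in the closed phase a Lamb-Oseen-like
#' vortex patch appears on the opposite side. Optional fo/3 gate
#' modulation produces a subharmonic family, and band-limited seeded
#' fluctuations model turbulence. The amplitude is calibrated so the
#' time-mean volume flux through the inlet column equals
#' `mean_flow_rate`.
#'
#' All deterministic building blocks depend on time only through the cycle
#' phase, so with `turbulence_level = 0` and `subharmonic_fraction = 0` the
#' field is exactly periodic at `fo`.
#'
#' @param cfg A [flow_config()].
#' @return A `velocity_field_series`: list with `x`, `y` (m), `t` (s), `u`,
#'   `v` (arrays indexed time x y x x, m/s), `sample_rate`, and `config`.
#' @examples
#' f <- generate_velocity_series(flow_config(duration = 0.05, fo = 125))
#' dim(f$u)
#' @export
generate_velocity_series <- function(cfg) {
  if (!inherits(cfg, "flow_config")) stop("`cfg` must be a `flow_config`", call. = FALSE)
  nt <- round(cfg$duration * cfg$sample_rate)
  x <- seq(0, cfg$domain_width, length.out = cfg$nx)
  y <- seq(-cfg$domain_height / 2, cfg$domain_height / 2, length.out = cfg$ny)
  t <- (seq_len(nt) - 1L) / cfg$sample_rate

  phase <- (cfg$fo * t) %% 1            # cycle phase in [0, 1)
  gate <- pmax(0, sin(2 * pi * phase))^2
  if (cfg$subharmonic_fraction > 0) {
    phase3 <- (cfg$fo * t / 3) %% 1     # fo/3-periodic modulation
    gate <- gate * (1 + cfg$subharmonic_fraction * sin(2 * pi * phase3))
  }
  # wall-ward drift: ramps up through the closing phase, peaks at closure
  defl <- pmax(0, sin(2 * pi * phase - pi / 2))
  # vortex envelope: active during the closed phase
  vtx <- pmax(0, -sin(2 * pi * phase))

  ang <- cfg$deflection_angle * pi / 180
  # initial half-width sized so the calibrated peak velocity lands near the
  # Bernoulli velocity sqrt(2 dp / rho0) ~ 84 m/s at the benchmark operating
  # point (124 l/min, 4.2 kPa)
  w0 <- 0.0035
  spread <- 0.15                        # half-width growth per unit x
  wx <- w0 + spread * x
  U0 <- cfg$jet_peak_velocity

  # vortex patch geometry (opposite wall, mid-channel, drifting downstream)
  rc <- 0.004
  yv <- -sign(ang + (ang == 0)) * 0.004
  Gamma0 <- cfg$vortex_strength * U0 * 2 * pi * rc

  u <- array(0, dim = c(nt, cfg$ny, cfg$nx))
  v <- array(0, dim = c(nt, cfg$ny, cfg$nx))
  for (it in seq_len(nt)) {
    yc <- tan(ang) * x * defl[it]                 # centreline per x column
    prof <- exp(-((matrix(y, cfg$ny, cfg$nx) -
                     matrix(yc, cfg$ny, cfg$nx, byrow = TRUE)) /
                    matrix(wx, cfg$ny, cfg$nx, byrow = TRUE))^2)
    ui <- U0 * gate[it] * prof
    vi <- ui * tan(ang) * defl[it]
    if (vtx[it] > 0 && cfg$vortex_strength > 0) {
      xv <- 0.010 + 0.015 * phase[it]
      dx <- matrix(x - xv, cfg$ny, cfg$nx, byrow = TRUE)
      dy <- matrix(y - yv, cfg$ny, cfg$nx)
      r2 <- dx^2 + dy^2
      r2[r2 < 1e-10] <- 1e-10
      utheta <- Gamma0 * vtx[it] / (2 * pi * sqrt(r2)) * (1 - exp(-r2 / rc^2))
      ui <- ui - utheta * dy / sqrt(r2)
      vi <- vi + utheta * dx / sqrt(r2)
    }
    u[it, , ] <- ui
    v[it, , ] <- vi
  }

  # flux calibration: time-mean volume flux through the inlet column
  depth <- cfg$duct_area / cfg$domain_height
  inlet_flux <- apply(u[, , 1L, drop = FALSE], 1L, function(col) pracma::trapz(y, col))
  mean_flux <- mean(inlet_flux) * depth
  if (mean_flux <= 0) stop("degenerate jet: non-positive mean inlet flux", call. = FALSE)
  scale <- cfg$mean_flow_rate / mean_flux
  u <- u * scale
  v <- v * scale

  if (cfg$turbulence_level > 0) {
    set.seed(cfg$seed)
    amp <- cfg$turbulence_level * max(abs(u))
    u <- u + amp * band_limited_noise(nt, cfg$ny, cfg$nx)
    v <- v + amp * band_limited_noise(nt, cfg$ny, cfg$nx)
  }

  structure(list(x = x, y = y, t = t, u = u, v = v,
                 sample_rate = cfg$sample_rate, config = cfg),
            class = "velocity_field_series")
}

# Fluctuation field, band-limited in time (4-sample moving average,
# cutting content above ~fs/4) and correlated over ~1 grid cell in space
# (3-point smoothing along both axes). The temporal mean is removed per
# grid point: turbulence is a zero-mean fluctuation about the phase-locked
# flow, which also keeps the mean-flux calibration exact.
band_limited_noise <- function(nt, ny, nx) {
  n <- array(stats::rnorm(nt * ny * nx), dim = c(nt, ny, nx))
  m <- matrix(n, nt, ny * nx)
  m <- (m + rbind(m[-1, , drop = FALSE], m[1, , drop = FALSE]) +
          rbind(m[nt, , drop = FALSE], m[-nt, , drop = FALSE]) +
          rbind(m[c(nt - 1L, nt), , drop = FALSE], m[seq_len(nt - 2L), , drop = FALSE])) / 4
  m <- sweep(m, 2L, colMeans(m))
  n <- array(m, dim = c(nt, ny, nx))
  n <- (n[, c(1L, seq_len(ny - 1L)), ] + n + n[, c(seq_len(ny - 1L) + 1L, ny), ]) / 3
  n <- (n[, , c(1L, seq_len(nx - 1L))] + n + n[, , c(seq_len(nx - 1L) + 1L, nx)]) / 3
  n / stats::sd(n)
}

#' @export
print.velocity_field_series <- function(x, ...) {
  cat(sprintf("Velocity field series: %d steps @ %g Hz, grid %d x %d (%g x %g mm)\n",
              length(x$t), x$sample_rate, length(x$x), length(x$y),
              1000 * diff(range(x$x)), 1000 * diff(range(x$y))))
  invisible(x)
}

#' Bulk velocity recovered from a velocity-field series
#'
#' Time-mean volume flux through the inlet column divided by the duct area,
#' i.e. the bulk (duct-average) velocity `U = V' / S` implied by the field.
#'
#' @param field A `velocity_field_series`.
#' @return Bulk velocity in m/s.
#' @export
measure_bulk_velocity <- function(field) {
  stopifnot(inherits(field, "velocity_field_series"))
  cfg <- field$config
  depth <- cfg$duct_area / cfg$domain_height
  flux <- apply(field$u[, , 1L, drop = FALSE], 1L,
                function(col) pracma::trapz(field$y, col))
  mean(flux) * depth / cfg$duct_area
}
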