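#' Configuration for the synthetic particle-image generator
#'
#' Emulates raw PIV recordings: Gaussian tracer-particle blobs over a static
#' low-frequency background, a bright reflection band near a periodically
#' moving vocal-fold silhouette at the left image edge, and Gaussian sensor
#' noise.
#'
#' @param width,height Frame size in pixels.
#' @param n_frames Number of frames (>= 2).
#' @param particle_density Particles per pixel (e.g. 0.02).
#' @param particle_diameter Particle image diameter, pixels (Gaussian blobs
#'   with sigma = diameter / 2.355, i.e. diameter read at FWHM).
#' @param particle_intensity Peak blob intensity.
#' @param background_amplitude Amplitude of the static smooth background.
#' @param reflection_amplitude Peak intensity of the bright reflection band.
#' @param reflection_center_px Mean x-position of the band, pixels from the
#'   left edge.
#' @param reflection_width_px Gaussian half-width of the band, pixels.
#' @param reflection_osc_px Oscillation amplitude of the band position,
#'   pixels (fo-periodic silhouette motion).
#' @param frames_per_cycle Frames per silhouette oscillation cycle.
#' @param sensor_noise_sigma Gaussian sensor-noise standard deviation.
#' @param jitter_px RMS random particle displacement between frames when no
#'   velocity field is supplied, pixels.
#' @param seed Integer seed.
#'
#' @return An `image_stack_config` list.
#' @export
image_stack_config <- function(width = 96L, height = 64L, n_frames = 12L,
                               particle_density = 0.02, particle_diameter = 3,
                               particle_intensity = 0.25,
                               background_amplitude = 0.3,
                               reflection_amplitude = 1,
                               reflection_center_px = 10,
                               reflection_width_px = 4,
                               reflection_osc_px = 2,
                               frames_per_cycle = 8,
                               sensor_noise_sigma = 0.02,
                               jitter_px = 0.5, seed = 1L) {
  cfg <- list(width = as.integer(width), height = as.integer(height),
              n_frames = as.integer(n_frames),
              particle_density = particle_density,
              particle_diameter = particle_diameter,
              particle_intensity = particle_intensity,
              background_amplitude = background_amplitude,
              reflection_amplitude = reflection_amplitude,
              reflection_center_px = reflection_center_px,
              reflection_width_px = reflection_width_px,
              reflection_osc_px = reflection_osc_px,
              frames_per_cycle = frames_per_cycle,
              sensor_noise_sigma = sensor_noise_sigma,
              jitter_px = jitter_px, seed = as.integer(seed))
  if (cfg$n_frames < 2L)
    stop("image config: need at least 2 frames", call. = FALSE)
  amps <- c(cfg$particle_density, cfg$particle_intensity,
            cfg$background_amplitude, cfg$reflection_amplitude,
            cfg$sensor_noise_sigma)
  if (any(amps < 0))
    stop("image config: densities and amplitudes must be >= 0", call. = FALSE)
  structure(cfg, class = "image_stack_config")
}

#' Generate a synthetic particle-image stack with known ground truth
#'
#' The emitted frames are built strictly additively:
#' `frames = particles + background + reflections + noise`, and every
#' component stack is returned alongside, so conditioning algorithms can be
#' scored against the particle-only ground truth exactly.
#'
#' When a [generate_velocity_series()] field is supplied, particles are
#' advected by the local velocity sampled at their position (one field time
#' step per frame, displacement scaled by `advection_px_per_ms`); otherwise
#' they random-walk with `jitter_px`.
#'
#' @param cfg An [image_stack_config()].
#' @param field Optional `velocity_field_series` used to advect particles.
#' @param advection_px_per_ms Pixel displacement per frame per (m/s) of
#'   local velocity.
#' @return An `image_stack`: list with `frames`, `particles`, `background`,
#'   `reflections`, `noise` (arrays n_frames x height x width) and `config`.
#' @export
generate_particle_images <- function(cfg, field = NULL,
                                     advection_px_per_ms = 0.1) {
  if (!inherits(cfg, "image_stack_config"))
    stop("`cfg` must be an `image_stack_config`", call. = FALSE)
  set.seed(cfg$seed)
  h <- cfg$height; w <- cfg$width; nf <- cfg$n_frames
  npart <- round(cfg$particle_density * h * w)
  px <- stats::runif(npart, 1, w)
  py <- stats::runif(npart, 1, h)
  sig <- cfg$particle_diameter / 2.355

  xs <- seq_len(w); ys <- seq_len(h)
  background <- cfg$background_amplitude *
    (0.5 + 0.25 * outer(sin(2 * pi * ys / h), cos(2 * pi * xs / w)) +
       0.25 * matrix(xs, h, w, byrow = TRUE) / w)

  particles <- array(0, dim = c(nf, h, w))
  reflections <- array(0, dim = c(nf, h, w))
  noise <- array(0, dim = c(nf, h, w))
  half <- ceiling(3 * sig)
  for (fr in seq_len(nf)) {
    frame <- matrix(0, h, w)
    for (p in seq_len(npart)) {
      cx <- px[p]; cy <- py[p]
      ix <- max(1L, floor(cx - half)):min(w, ceiling(cx + half))
      iy <- max(1L, floor(cy - half)):min(h, ceiling(cy + half))
      if (!length(ix) || !length(iy)) next
      frame[iy, ix] <- frame[iy, ix] + cfg$particle_intensity *
        outer(exp(-(iy - cy)^2 / (2 * sig^2)), exp(-(ix - cx)^2 / (2 * sig^2)))
    }
    particles[fr, , ] <- frame

    xb <- cfg$reflection_center_px +
      cfg$reflection_osc_px * sin(2 * pi * (fr - 1L) / cfg$frames_per_cycle)
    band <- exp(-((xs - xb) / cfg$reflection_width_px)^2)
    reflections[fr, , ] <- cfg$reflection_amplitude *
      matrix(band, h, w, byrow = TRUE)

    if (cfg$sensor_noise_sigma > 0)
      noise[fr, , ] <- cfg$sensor_noise_sigma * matrix(stats::rnorm(h * w), h, w)

    # move particles for the next frame
    if (fr < nf) {
      if (!is.null(field)) {
        it <- ((fr - 1L) %% length(field$t)) + 1L
        fx <- stats::approx(seq(0, 1, length.out = length(field$x)),
                            seq_along(field$x), (px - 1) / (w - 1), rule = 2)$y
        fy <- stats::approx(seq(0, 1, length.out = length(field$y)),
                            seq_along(field$y), (py - 1) / (h - 1), rule = 2)$y
        ui <- field$u[it, , ]; vi <- field$v[it, , ]
        uloc <- ui[cbind(pmin(pmax(round(fy), 1), length(field$y)),
                         pmin(pmax(round(fx), 1), length(field$x)))]
        vloc <- vi[cbind(pmin(pmax(round(fy), 1), length(field$y)),
                         pmin(pmax(round(fx), 1), length(field$x)))]
        px <- px + advection_px_per_ms * uloc
        py <- py + advection_px_per_ms * vloc
      } else if (cfg$jitter_px > 0) {
        px <- px + cfg$jitter_px * stats::rnorm(npart)
        py <- py + cfg$jitter_px * stats::rnorm(npart)
      }
      px <- ((px - 1) %% w) + 1
      py <- ((py - 1) %% h) + 1
    }
  }

  bg_stack <- array(rep(background, each = nf), dim = c(nf, h, w))
  frames <- particles + bg_stack + reflections + noise
  structure(list(frames = frames, particles = particles,
                 background = bg_stack, reflections = reflections,
                 noise = noise, config = cfg),
            class = "image_stack")
}

#' Image stack container
#'
#' Wrap an array of frames as an `image_stack` as produced by
#' [generate_particle_images()] (conditioning functions accept either the
#' full object or a bare array).
#'
#' @param frames Array `n_frames x height x width`, finite and >= 0 values.
#' @param frame_rate Frames per second (optional metadata).
#' @return An `image_stack`.
#' @export
image_stack <- function(frames, frame_rate = NA_real_) {
  if (length(dim(frames)) != 3L || dim(frames)[1] < 2L)
    stop("`frames` must be an array with at least 2 frames", call. = FALSE)
  if (any(!is.finite(frames)))
    stop("frame intensities must be finite", call. = FALSE)
  structure(list(frames = frames, frame_rate = frame_rate),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Image stack: %d frames of %d x %d px\n", d[1], d[2], d[3]))
  invisible(x)
}

stack_frames <- function(stack) {
  if (inherits(stack, "image_stack")) stack$frames
  else if (is.array(stack) && length(dim(stack)) == 3L) stack
  else stop("expected an `image_stack` or a 3-d array", call. = FALSE)
}
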