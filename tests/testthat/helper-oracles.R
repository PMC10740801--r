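# Independent oracles and small fixture builders used across the suite.

# Wrap plain component arrays as a velocity_field_series on a physical grid.
make_field <- function(u, v, dx = 5e-4, dy = 3e-4, fs = 5000) {
  if (length(dim(u)) == 2L) {
    u <- array(u, dim = c(1L, nrow(u), ncol(u)))
    v <- array(v, dim = c(1L, nrow(v), ncol(v)))
  }
  d <- dim(u)
  structure(list(
    x = (seq_len(d[3]) - 1L) * dx,
    y = ((seq_len(d[2]) - 1L) - (d[2] - 1L) / 2) * dy,
    t = (seq_len(d[1]) - 1L) / fs,
    u = u, v = v, sample_rate = fs, config = NULL
  ), class = "velocity_field_series")
}

# Random smooth planar field: a handful of low-wavenumber sinusoids.
smooth_component <- function(nx, ny, dx, dy, n_modes = 4L) {
  x <- (seq_len(nx) - 1L) * dx
  y <- (seq_len(ny) - 1L) * dy
  M <- matrix(0, ny, nx)
  for (k in seq_len(n_modes)) {
    px <- stats::runif(1, 0.2, 1) / (nx * dx)
    py <- stats::runif(1, 0.2, 1) / (ny * dy)
    ph <- stats::runif(2, 0, 2 * pi)
    M <- M + stats::runif(1, 0.5, 2) *
      outer(sin(2 * pi * py * y + ph[1]), sin(2 * pi * px * x + ph[2]))
  }
  M
}

# Double-divergence Lighthill oracle: explicit index loops, second-order
# one-sided borders, first-derivative stencil applied twice. Deliberately
# written with scalar loops, independent of the package's vectorised path.
oracle_lighthill <- function(u, v, dx, dy, rho0 = 1.2) {
  ddx <- function(M, h) {
    ny <- nrow(M); nx <- ncol(M); out <- matrix(0, ny, nx)
    for (i in seq_len(ny)) for (j in seq_len(nx)) {
      out[i, j] <-
        if (j == 1L) (-3 * M[i, 1] + 4 * M[i, 2] - M[i, 3]) / (2 * h)
        else if (j == nx) (3 * M[i, nx] - 4 * M[i, nx - 1] + M[i, nx - 2]) / (2 * h)
        else (M[i, j + 1] - M[i, j - 1]) / (2 * h)
    }
    out
  }
  ddy <- function(M, h) {
    ny <- nrow(M); nx <- ncol(M); out <- matrix(0, ny, nx)
    for (i in seq_len(ny)) for (j in seq_len(nx)) {
      out[i, j] <-
        if (i == 1L) (-3 * M[1, j] + 4 * M[2, j] - M[3, j]) / (2 * h)
        else if (i == ny) (3 * M[ny, j] - 4 * M[ny - 1, j] + M[ny - 2, j]) / (2 * h)
        else (M[i + 1, j] - M[i - 1, j]) / (2 * h)
    }
    out
  }
  m11 <- rho0 * u * u; m12 <- rho0 * u * v; m22 <- rho0 * v * v
  f1 <- ddx(m11, dx) + ddy(m12, dy)
  f2 <- ddx(m12, dx) + ddy(m22, dy)
  ddx(f1, dx) + ddy(f2, dy)
}

# Brute-force normalized-median flags, built from NA-padded shift stacks
# rather than per-point neighbourhood extraction.
oracle_nmt_flags <- function(u, v, threshold = 2, eps = 0.1) {
  ny <- nrow(u); nx <- ncol(u)
  shifts <- expand.grid(di = -1:1, dj = -1:1)
  shifts <- shifts[!(shifts$di == 0 & shifts$dj == 0), ]
  stack_of <- function(M) {
    s <- array(NA_real_, dim = c(ny, nx, nrow(shifts)))
    for (k in seq_len(nrow(shifts))) {
      di <- shifts$di[k]; dj <- shifts$dj[k]
      si <- seq_len(ny) + di; sj <- seq_len(nx) + dj
      ok_i <- si >= 1 & si <= ny; ok_j <- sj >= 1 & sj <= nx
      s[ok_i, ok_j, k] <- M[si[ok_i], sj[ok_j]]
    }
    s
  }
  rstar <- function(M) {
    s <- stack_of(M)
    med <- apply(s, c(1, 2), stats::median, na.rm = TRUE)
    rmed <- apply(sweep(s, c(1, 2), med), c(1, 2),
                  function(r) stats::median(abs(r), na.rm = TRUE))
    abs(M - med) / (rmed + eps)
  }
  pmax(rstar(u), rstar(v)) > threshold
}

# Simple Lorentzian impedance spectrum with a known analytic peak.
lorentzian_spectrum <- function(f, fp, gamma) {
  z <- 1 / complex(real = (f - fp), imaginary = gamma)
  structure(list(frequencies = f, Zin = z), class = "impedance_spectrum")
}
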