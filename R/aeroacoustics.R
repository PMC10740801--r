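# First derivative on a regular grid, second order: central differences in
# the interior, one-sided three-point stencils at the borders. Operates
# along rows (dim 1) of a matrix.
deriv1_rows <- function(M, h) {
  n <- nrow(M)
  D <- matrix(0, n, ncol(M))
  D[2:(n - 1L), ] <- (M[3:n, , drop = FALSE] - M[1:(n - 2L), , drop = FALSE]) / (2 * h)
  D[1L, ] <- (-3 * M[1L, ] + 4 * M[2L, ] - M[3L, ]) / (2 * h)
  D[n, ] <- (3 * M[n, ] - 4 * M[n - 1L, ] + M[n - 2L, ]) / (2 * h)
  D
}

d_dy <- function(M, dy) deriv1_rows(M, dy)            # y indexes rows
d_dx <- function(M, dx) t(deriv1_rows(t(M), dx))      # x indexes columns

#' Lighthill source-term field from a planar velocity series
#'
#' Computes the low-Mach isentropic Lighthill source term
#' `T = div(div(rho0 u u))`, i.e. the double divergence of the momentum
#' flux tensor restricted to the measurement plane:
#' `T = d2(rho0 u^2)/dx2 + 2 d2(rho0 u v)/dxdy + d2(rho0 v^2)/dy2`.
#' The operator is evaluated as two successive discrete divergences with
#' second-order first-derivative stencils (central in the interior,
#' one-sided at the borders), applied per time step.
#'
#' @param field A `velocity_field_series` (regular grid, >= 3 points per
#'   axis).
#' @param consts [acoustic_constants()] supplying `rho0`.
#' @param presmooth_sigma Optional Gaussian pre-filter width (grid cells)
#'   applied to `u` and `v` before differentiation; 0 (default) disables
#'   it. Useful for noisy PIV-like input.
#' @return A `source_field_series`: list with `T` (array time x y x x,
#'   Pa/m^2), grid metadata `x`, `y`, `t`, and `sample_rate`.
#' @export
lighthill_source_field <- function(field, consts = acoustic_constants(),
                                   presmooth_sigma = 0) {
  stopifnot(inherits(field, "velocity_field_series"))
  consts <- as_constants(consts)
  ny <- length(field$y); nx <- length(field$x)
  if (ny < 3L || nx < 3L)
    stop("grid must have at least 3 points per axis", call. = FALSE)
  dx <- field$x[2L] - field$x[1L]
  dy <- field$y[2L] - field$y[1L]
  nt <- length(field$t)
  TT <- array(0, dim = c(nt, ny, nx))
  for (it in seq_len(nt)) {
    u <- field$u[it, , ]
    v <- field$v[it, , ]
    if (presmooth_sigma > 0) {
      u <- gauss_smooth2(u, presmooth_sigma)
      v <- gauss_smooth2(v, presmooth_sigma)
    }
    m11 <- consts$rho0 * u * u
    m12 <- consts$rho0 * u * v
    m22 <- consts$rho0 * v * v
    f1 <- d_dx(m11, dx) + d_dy(m12, dy)   # first divergence, x row of the tensor
    f2 <- d_dx(m12, dx) + d_dy(m22, dy)   # first divergence, y row
    TT[it, , ] <- d_dx(f1, dx) + d_dy(f2, dy)
  }
  structure(list(T = TT, x = field$x, y = field$y, t = field$t,
                 sample_rate = field$sample_rate),
            class = "source_field_series")
}

gauss_smooth2 <- function(M, sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  sm_rows <- function(A) {
    n <- nrow(A)
    out <- matrix(0, n, ncol(A))
    for (o in seq(-r, r)) {
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)
      out <- out + k[o + r + 1L] * A[idx, , drop = FALSE]
    }
    out
  }
  t(sm_rows(t(sm_rows(M))))
}

#' @export
print.source_field_series <- function(x, ...) {
  cat(sprintf("Lighthill source field: %d steps, grid %d x %d\n",
              length(x$t), length(x$y), length(x$x)))
  invisible(x)
}

#' Region-of-interest bounds for source aggregation
#'
#' @param x0,x1,y0,y1 Bounding coordinates of the region of interest, m.
#' @param Nx,Ny Grid vector counts inside the ROI.
#' @param observer_distance Virtual observer distance, m (default 1;
#'   absorbed into the aggregated source definition).
#' @return A `roi_bounds` list.
#' @export
roi_bounds <- function(x0, x1, y0, y1, Nx, Ny, observer_distance = 1) {
  if (x1 <= x0 || y1 <= y0)
    stop("ROI bounds must satisfy x1 > x0 and y1 > y0", call. = FALSE)
  structure(list(x0 = x0, x1 = x1, y0 = y0, y1 = y1,
                 Nx = as.integer(Nx), Ny = as.integer(Ny),
                 observer_distance = observer_distance),
            class = "roi_bounds")
}

#' @rdname roi_bounds
#' @param src A `source_field_series` or `velocity_field_series` whose grid
#'   defines the ROI.
#' @export
roi_from_field <- function(src, observer_distance = 1) {
  roi_bounds(min(src$x), max(src$x), min(src$y), max(src$y),
             length(src$x), length(src$y), observer_distance)
}

#' Aggregate the source field into a summed source signal
#'
#' Collapses the distributed source term into a single time series using
#' the axisymmetric weighting around the duct axis:
#' `phi(t) = 1 / (4 c0^2 Nx Ny) * sum_i T(x_i, t) |y_i|`, with `y`
#' measured from the duct axis and the 1 m observer distance absorbed into
#' the prefactor. The RMS over the full record is attached as `Phi`.
#'
#' @param src A `source_field_series` from [lighthill_source_field()].
#' @param roi A [roi_bounds()]; must match the source grid counts.
#' @param consts [acoustic_constants()].
#' @return A `source_signal`: list with `t`, `phi`, `Phi` and
#'   `sample_rate`.
#' @export
summed_source_signal <- function(src, roi = roi_from_field(src),
                                 consts = acoustic_constants()) {
  stopifnot(inherits(src, "source_field_series"))
  consts <- as_constants(consts)
  ny <- length(src$y); nx <- length(src$x)
  if (roi$Nx != nx || roi$Ny != ny)
    stop("ROI grid counts do not match the source field", call. = FALSE)
  wy <- abs(src$y)                       # axisymmetry weight |y|
  pref <- 1 / (4 * consts$c0^2 * roi$Nx * roi$Ny)
  nt <- length(src$t)
  M <- matrix(src$T, nt, ny * nx)
  phi <- pref * as.numeric(M %*% rep(wy, times = nx))
  Phi <- if (nt >= 2L)
    rms_source_strength_raw(src$t, phi, src$t[1L], src$t[nt]) else abs(phi)
  structure(list(t = src$t, phi = phi, Phi = Phi, sample_rate = src$sample_rate),
            class = "source_signal")
}

#' @export
print.source_signal <- function(x, ...) {
  cat(sprintf("Summed source signal: %d steps, Phi (rms) = %.4g\n",
              length(x$t), x$Phi))
  invisible(x)
}

rms_source_strength_raw <- function(t, phi, t0, t1) {
  sel <- t >= t0 & t <= t1
  if (sum(sel) < 2L) stop("integration window is empty", call. = FALSE)
  sqrt(pracma::trapz(t[sel], phi[sel]^2) / (t[sel][sum(sel)] - t[sel][1L]))
}

#' RMS source strength over a time window
#'
#' `Phi = sqrt( 1/(t1 - t0) * integral of phi^2 dt )`, by trapezoidal
#' integration on the native time grid.
#'
#' @param sig A `source_signal` from [summed_source_signal()].
#' @param t0,t1 Integration window, within the signal support, `t1 > t0`.
#'   Defaults to the full record.
#' @return The scalar RMS source strength.
#' @export
rms_source_strength <- function(sig, t0 = min(sig$t), t1 = max(sig$t)) {
  stopifnot(inherits(sig, "source_signal"))
  if (t1 <= t0) stop("need t1 > t0", call. = FALSE)
  if (t0 < min(sig$t) - 1e-12 || t1 > max(sig$t) + 1e-12)
    stop("window outside the signal support", call. = FALSE)
  rms_source_strength_raw(sig$t, sig$phi, t0, t1)
}

#' Total aerodynamic input pressure
#'
#' `P = dp + 1/2 rho0 U^2`: the driving (subglottal) pressure plus the
#' dynamic head of the bulk duct flow. `U` is typically the bulk velocity
#' `V' / S`.
#'
#' @param dp Driving pressure difference, Pa (subglottal minus ambient by
#'   default convention; the transglottal difference may be supplied
#'   instead, whichever the study defines as the input).
#' @param U Bulk velocity, m/s.
#' @param consts [acoustic_constants()].
#' @return Total input pressure `P`, Pa.
#' @examples
#' aerodynamic_input_power(4208, (124 / 60000) / 2.7e-4)
#' @export
aerodynamic_input_power <- function(dp, U, consts = acoustic_constants()) {
  consts <- as_constants(consts)
  dp + 0.5 * consts$rho0 * U^2
}

#' Aeroacoustic efficiency
#'
#' `eta = Phi c0^2 (x1 - x0) (y1 - y0) / P`: the RMS aggregated source
#' strength scaled by the ROI area against the aerodynamic input. The
#' value is a relative measure for comparing configurations, not an
#' absolute acoustic efficiency.
#'
#' @param Phi RMS source strength from [rms_source_strength()].
#' @param roi A [roi_bounds()].
#' @param P Total input pressure from [aerodynamic_input_power()]; must be
#'   positive.
#' @param consts [acoustic_constants()].
#' @return The efficiency `eta` (dimensionless in the sense above).
#' @export
aeroacoustic_efficiency <- function(Phi, roi, P, consts = acoustic_constants()) {
  consts <- as_constants(consts)
  stopifnot(inherits(roi, "roi_bounds"))
  if (P <= 0) stop("`P` must be positive", call. = FALSE)
  Phi * consts$c0^2 * (roi$x1 - roi$x0) * (roi$y1 - roi$y0) / P
}

#' Fifth-power (Mach-number) efficiency prediction
#'
#' Theoretical efficiency of free turbulent jets scales with the fifth
#' power of the Mach number. Anchored so the prediction equals `eta_ref`
#' at `U_ref`: `eta_theor(U) = eta_ref (U / U_ref)^5`.
#'
#' @param eta_ref Efficiency at the reference bulk velocity.
#' @param U_ref Reference bulk velocity, m/s, > 0.
#' @param U Bulk velocities to predict at (vectorised), m/s.
#' @param consts [acoustic_constants()] (the speed of sound cancels in the
#'   anchored ratio; accepted for interface uniformity).
#' @return Predicted efficiencies, same length as `U`.
#' @examples
#' mach_fifth_power_prediction(1, 4, c(4, 8)) # anchored, then 2^5 = 32
#' @export
mach_fifth_power_prediction <- function(eta_ref, U_ref, U,
                                        consts = acoustic_constants()) {
  if (U_ref <= 0) stop("`U_ref` must be positive", call. = FALSE)
  eta_ref * (U / U_ref)^5
}
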