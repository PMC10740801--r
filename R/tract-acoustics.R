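#' Chain matrix of a uniform lossless tube section
#'
#' Two-port transmission matrix relating acoustic pressure and volume
#' velocity at the section output to those at the input,
#' `(p, u)_out = K (p, u)_in`, for plane-wave propagation in a rigid-walled
#' lossless tube. With `k = 2 pi f / c0` and characteristic impedance
#' `Zc = rho0 c0 / S`, the entries are
#' `A = D = cos(k l)`, `B = -i Zc sin(k l)`, `C = -i sin(k l) / Zc`.
#'
#' @param f Frequency in Hz, a single positive number.
#' @param section A [tube_section()].
#' @param consts [acoustic_constants()].
#'
#' @return A `chain_matrix`: a 2x2 complex matrix with entries A, B (top row)
#'   and C, D (bottom row).
#' @examples
#' s <- circ_section(0.1, 0.032)
#' K <- section_chain_matrix(500, s)
#' det(K) # reciprocity: A D - B C = 1 for a lossless section
#' @export
section_chain_matrix <- function(f, section, consts = acoustic_constants()) {
  consts <- as_constants(consts)
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0)
    stop("`f` must be a single positive frequency in Hz", call. = FALSE)
  stopifnot(inherits(section, "tube_section"))
  kl <- 2 * pi * f / consts$c0 * section$length
  Zc <- consts$rho0 * consts$c0 / section$area
  m <- matrix(c(cos(kl), -1i * sin(kl) / Zc,
                -1i * Zc * sin(kl), cos(kl)), 2L, 2L)
  structure(m, class = c("chain_matrix", class(m)))
}

# Vectorised ABCD entries of the full tract over a frequency vector.
# Product order: sections are traversed glottis -> mouth, each new section
# matrix multiplying from the left, so K_tract = K_n ... K_2 K_1.
tract_abcd <- function(f, geometry, consts) {
  A <- rep(1 + 0i, length(f)); B <- rep(0 + 0i, length(f))
  C <- rep(0 + 0i, length(f)); D <- rep(1 + 0i, length(f))
  for (s in geometry$sections) {
    kl <- 2 * pi * f / consts$c0 * s$length
    Zc <- consts$rho0 * consts$c0 / s$area
    a <- cos(kl); b <- -1i * Zc * sin(kl); cc <- -1i * sin(kl) / Zc
    A2 <- a * A + b * C;  B2 <- a * B + b * D
    C2 <- cc * A + a * C; D2 <- cc * B + a * D
    A <- A2; B <- B2; C <- C2; D <- D2
  }
  list(A = A, B = B, C = C, D = D)
}

#' Chain matrix of a full segmented tract
#'
#' Ordered product of the per-section chain matrices from the glottis to the
#' mouth: `K_tract = K_n ... K_2 K_1`, with section 1 at the glottis end.
#'
#' @inheritParams section_chain_matrix
#' @param geometry A [tract_geometry()].
#' @return A `chain_matrix`.
#' @export
tract_chain_matrix <- function(f, geometry, consts = acoustic_constants()) {
  consts <- as_constants(consts)
  if (!inherits(geometry, "tract_geometry"))
    stop("invalid geometry: expected a `tract_geometry`", call. = FALSE)
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0)
    stop("`f` must be a single positive frequency in Hz", call. = FALSE)
  e <- tract_abcd(f, geometry, consts)
  m <- matrix(c(e$A, e$C, e$B, e$D), 2L, 2L)
  structure(m, class = c("chain_matrix", class(m)))
}

#' Radiation impedance of a piston in an infinite baffle
#'
#' Acoustic load seen by the open duct end, modelled as a rigid circular
#' piston of the outlet area vibrating in an infinite baffle:
#' `Z_out = (rho0 c0 / S) (R + i X)`. The default low-`ka` approximation uses
#' `R = (ka)^2 / 2` and `X = 8 ka / (3 pi)` with the equivalent piston radius
#' `a = sqrt(S / pi)`; `method = "exact"` evaluates the full Bessel/Struve
#' form `R = 1 - 2 J1(2ka) / (2ka)`, `X = 2 H1(2ka) / (2ka)`.
#'
#' @param f Frequency in Hz (vectorised), > 0.
#' @param outlet_area Outlet cross-sectional area in m^2.
#' @param consts [acoustic_constants()].
#' @param method `"low_ka"` (default) or `"exact"`.
#'
#' @return Complex impedance (Pa s / m^3), same length as `f`.
#' @examples
#' radiation_impedance(500, pi * 0.017^2)
#' @export
radiation_impedance <- function(f, outlet_area, consts = acoustic_constants(),
                                method = c("low_ka", "exact")) {
  consts <- as_constants(consts)
  method <- match.arg(method)
  if (any(!is.finite(f)) || any(f <= 0))
    stop("`f` must be positive", call. = FALSE)
  if (!is.numeric(outlet_area) || outlet_area <= 0)
    stop("`outlet_area` must be positive", call. = FALSE)
  a <- sqrt(outlet_area / pi)
  ka <- 2 * pi * f / consts$c0 * a
  if (method == "low_ka") {
    R <- ka^2 / 2
    X <- 8 * ka / (3 * pi)
  } else {
    x <- 2 * ka
    R <- 1 - 2 * besselJ(x, 1) / x
    X <- 2 * struve_h1(x) / x
  }
  (consts$rho0 * consts$c0 / outlet_area) * (R + 1i * X)
}

# Struve function H1 by its ascending power series,
# H1(x) = sum_{m>=0} (-1)^m (x/2)^(2m+2) / (Gamma(m+3/2) Gamma(m+5/2)).
# Accurate for the moderate arguments (x <~ 20) relevant to duct radiation.
struve_h1 <- function(x) {
  out <- numeric(length(x))
  half <- (x / 2)^2
  term <- half / (gamma(1.5) * gamma(2.5))
  s <- term
  for (m in seq_len(40L)) {
    term <- -term * half / ((m + 0.5) * (m + 1.5))
    s <- s + term
  }
  out <- s
  out
}

resolve_load <- function(f, geometry, consts, load, radiation_method) {
  switch(load,
         piston = radiation_impedance(
           f, geometry$sections[[length(geometry$sections)]]$area,
           consts, method = radiation_method),
         none = rep(0 + 0i, length(f)),
         stop("unknown `load`", call. = FALSE))
}

#' Input impedance of the tract at the glottis
#'
#' Evaluates `Zin = (D Zout - B) / (A - C Zout)` from the tract chain matrix
#' and the mouth radiation load. A vanishing denominator (a pole of the
#' lossless system) is reported as an infinite-magnitude value, not an error.
#'
#' @param f Frequency in Hz (vectorised), > 0.
#' @param geometry A [tract_geometry()].
#' @param consts [acoustic_constants()].
#' @param load Termination at the mouth: `"piston"` (radiation impedance of a
#'   baffled piston, the default) or `"none"` (pressure-release end,
#'   `Zout = 0`, the ideal open termination).
#' @param radiation_method Passed to [radiation_impedance()].
#'
#' @return Complex input impedance, same length as `f`.
#' @examples
#' g <- build_geometry(0.2)
#' abs(input_impedance(c(100, 500), g))
#' @export
input_impedance <- function(f, geometry, consts = acoustic_constants(),
                            load = c("piston", "none"),
                            radiation_method = c("low_ka", "exact")) {
  consts <- as_constants(consts)
  load <- match.arg(load)
  radiation_method <- match.arg(radiation_method)
  if (!inherits(geometry, "tract_geometry"))
    stop("invalid geometry: expected a `tract_geometry`", call. = FALSE)
  if (any(!is.finite(f)) || any(f <= 0))
    stop("`f` must be positive", call. = FALSE)
  e <- tract_abcd(f, geometry, consts)
  Zout <- resolve_load(f, geometry, consts, load, radiation_method)
  num <- e$D * Zout - e$B
  den <- e$A - e$C * Zout
  z <- num / den
  z[den == 0] <- complex(real = Inf, imaginary = 0)
  z
}

#' Input-impedance spectrum over a frequency grid
#'
#' @param geometry A [tract_geometry()].
#' @param f_grid Strictly increasing frequency grid in Hz. The default covers
#'   20-1000 Hz at 0.25 Hz, fine enough to place the lower resonances to
#'   sub-Hz accuracy after parabolic refinement.
#' @inheritParams input_impedance
#'
#' @return An `impedance_spectrum`: list with `frequencies` (Hz) and `Zin`
#'   (complex).
#' @export
impedance_spectrum <- function(geometry, f_grid = seq(20, 1000, by = 0.25),
                               consts = acoustic_constants(),
                               load = c("piston", "none"),
                               radiation_method = c("low_ka", "exact")) {
  load <- match.arg(load)
  radiation_method <- match.arg(radiation_method)
  if (length(f_grid) < 2L || any(diff(f_grid) <= 0))
    stop("`f_grid` must be strictly increasing", call. = FALSE)
  z <- input_impedance(f_grid, geometry, consts, load, radiation_method)
  structure(list(frequencies = f_grid, Zin = z), class = "impedance_spectrum")
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf("Impedance spectrum: %d frequencies, %.6g-%.6g Hz\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' Extract resonance frequencies from an impedance spectrum
#'
#' Resonances are the local maxima of `|Zin|`. Each grid maximum is refined
#' by a three-point parabolic fit on `log10 |Zin|`; candidates at the grid
#' ends are not refined beyond the grid. Returned ascending, so the first
#' element is the first resonance fR1. Ties resolve to the lowest frequency
#' simply because maxima are scanned in ascending order.
#'
#' @param spectrum An `impedance_spectrum` from [impedance_spectrum()].
#' @return A `resonance_set`: list with `resonances`, an ascending numeric
#'   vector in Hz (possibly empty).
#' @examples
#' g <- tract_geometry(list(circ_section(0.857, 0.03)))
#' find_resonances(impedance_spectrum(g, load = "none"))$resonances[1]
#' @export
find_resonances <- function(spectrum) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  f <- spectrum$frequencies
  y <- log10(abs(spectrum$Zin))
  y[!is.finite(y)] <- max(y[is.finite(y)], 0) + 16 # poles dominate any finite peak
  n <- length(y)
  if (n < 3L)
    return(structure(list(resonances = numeric(0)), class = "resonance_set"))
  i <- which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
  if (!length(i))
    return(structure(list(resonances = numeric(0)), class = "resonance_set"))
  res <- vapply(i, function(j) {
    y0 <- y[j - 1L]; y1 <- y[j]; y2 <- y[j + 1L]
    den <- y0 - 2 * y1 + y2
    d <- if (den == 0) 0 else 0.5 * (y0 - y2) / den
    d <- max(-0.5, min(0.5, d))
    f[j] + d * (f[j + 1L] - f[j])
  }, numeric(1))
  structure(list(resonances = sort(res)), class = "resonance_set")
}

#' @export
print.resonance_set <- function(x, ...) {
  if (!length(x$resonances)) {
    cat("Resonance set: none found\n")
  } else {
    cat("Resonances (Hz):", paste(sprintf("%.1f", x$resonances), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Impedance magnitude map over a length sweep
#'
#' Evaluates `|Zin|(f)` for each requested total tract length (rows) and
#' tabulates the extracted resonances per length.
#'
#' @param L_grid Increasing vector of total lengths in metres.
#' @param f_grid Increasing frequency grid in Hz.
#' @param consts [acoustic_constants()].
#' @param config Geometry parameters, see [geometry_config()].
#' @param n_resonances Number of resonance columns in the table.
#' @inheritParams input_impedance
#'
#' @return An `impedance_map`: list with `L` (m), `frequencies` (Hz),
#'   `magnitude` (matrix, length x frequency), and `resonances`, a tibble
#'   with columns `L_mm`, `fR1_Hz`, `fR2_Hz`, ...
#' @export
impedance_map <- function(L_grid, f_grid = seq(20, 1000, by = 0.25),
                          consts = acoustic_constants(),
                          config = geometry_config(), n_resonances = 3L,
                          load = c("piston", "none"),
                          radiation_method = c("low_ka", "exact")) {
  load <- match.arg(load)
  radiation_method <- match.arg(radiation_method)
  if (any(diff(L_grid) <= 0) && length(L_grid) > 1L)
    stop("`L_grid` must be strictly increasing", call. = FALSE)
  mag <- matrix(NA_real_, length(L_grid), length(f_grid))
  res <- matrix(NA_real_, length(L_grid), n_resonances)
  for (k in seq_along(L_grid)) {
    g <- build_geometry(L_grid[k], config)
    sp <- impedance_spectrum(g, f_grid, consts, load, radiation_method)
    mag[k, ] <- abs(sp$Zin)
    r <- find_resonances(sp)$resonances
    res[k, seq_len(min(n_resonances, length(r)))] <- r[seq_len(min(n_resonances, length(r)))]
  }
  tab <- tibble::as_tibble(as.data.frame(res))
  names(tab) <- paste0("fR", seq_len(n_resonances), "_Hz")
  tab <- tibble::add_column(tab, L_mm = 1000 * L_grid, .before = 1L)
  structure(list(L = L_grid, frequencies = f_grid, magnitude = mag,
                 resonances = tab),
            class = "impedance_map")
}

#' @export
print.impedance_map <- function(x, ...) {
  cat(sprintf("Impedance map: %d lengths x %d frequencies\n",
              length(x$L), length(x$frequencies)))
  print(x$resonances)
  invisible(x)
}

#' Write a resonance table as CSV
#'
#' @param map An `impedance_map` (or its `$resonances` tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_resonance_table <- function(map, path) {
  tab <- if (inherits(map, "impedance_map")) map$resonances else map
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
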