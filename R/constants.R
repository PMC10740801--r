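#' Acoustic constants
#'
#' Bundle of the ambient-medium constants used throughout the transmission-line
#' and aeroacoustic computations.
#'
#' @param c0 Speed of sound in m/s. Default 343 (air at ~20 degrees C).
#' @param rho0 Air density in kg/m^3. Default 1.2.
#'
#' @return An object of class `acoustic_constants` with elements `c0` and
#'   `rho0`.
#' @examples
#' acoustic_constants()
#' acoustic_constants(c0 = 350)
#' @export
acoustic_constants <- function(c0 = 343, rho0 = 1.2) {
  if (!is.numeric(c0) || length(c0) != 1L || !is.finite(c0) || c0 <= 0)
    stop("`c0` must be a single positive number", call. = FALSE)
  if (!is.numeric(rho0) || length(rho0) != 1L || !is.finite(rho0) || rho0 <= 0)
    stop("`rho0` must be a single positive number", call. = FALSE)
  structure(list(c0 = c0, rho0 = rho0), class = "acoustic_constants")
}

#' @export
print.acoustic_constants <- function(x, ...) {
  cat("Acoustic constants: c0 =", x$c0, "m/s, rho0 =", x$rho0, "kg/m^3\n")
  invisible(x)
}

as_constants <- function(consts) {
  if (is.null(consts)) return(acoustic_constants())
  if (inherits(consts, "acoustic_constants")) return(consts)
  if (is.list(consts)) return(do.call(acoustic_constants, consts))
  stop("`consts` must be an `acoustic_constants` object or a list", call. = FALSE)
}
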