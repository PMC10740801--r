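#' Uniform tube section
#'
#' A single constant-cross-section element of a segmented duct. Sections are
#' the building blocks of a [tract_geometry()].
#'
#' @param length Section length in metres. Must be > 0.
#' @param area Cross-sectional area in square metres. Must be > 0.
#' @param shape Cross-section tag, `"rectangular"` or `"circular"`. Purely
#'   descriptive: the plane-wave model depends on the area only.
#' @param label Free-text label.
#'
#' @return An object of class `tube_section`.
#' @seealso [rect_section()], [circ_section()], [tract_geometry()]
#' @examples
#' tube_section(0.08, 2.7e-4, "rectangular", "supraglottal duct")
#' @export
tube_section <- function(length, area, shape = c("circular", "rectangular"),
                         label = "") {
  shape <- match.arg(shape)
  if (!is.numeric(length) || length(length) != 1L || !is.finite(length) || length <= 0)
    stop("section `length` must be a single positive number (metres)", call. = FALSE)
  if (!is.numeric(area) || length(area) != 1L || !is.finite(area) || area <= 0)
    stop("section `area` must be a single positive number (square metres)", call. = FALSE)
  structure(list(length = length, area = area, shape = shape,
                 label = as.character(label)[1L]),
            class = "tube_section")
}

#' @rdname tube_section
#' @param width,height Rectangular duct dimensions in metres.
#' @export
rect_section <- function(length, width, height, label = "") {
  tube_section(length, width * height, "rectangular", label)
}

#' @rdname tube_section
#' @param diameter Circular tube diameter in metres.
#' @export
circ_section <- function(length, diameter, label = "") {
  tube_section(length, pi * (diameter / 2)^2, "circular", label)
}

#' @export
print.tube_section <- function(x, ...) {
  cat(sprintf("Tube section%s: %s, length %.1f mm, area %.1f mm^2\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$shape, 1000 * x$length, 1e6 * x$area))
  invisible(x)
}

#' Segmented duct geometry
#'
#' An ordered sequence of uniform [tube_section()]s describing a vocal tract,
#' glottis end first and mouth (radiating) end last.
#'
#' @param sections A list of `tube_section` objects, ordered from the glottis
#'   to the mouth.
#'
#' @return An object of class `tract_geometry` with elements `sections` and
#'   `total_length` (metres).
#' @examples
#' g <- tract_geometry(list(
#'   rect_section(0.08, 0.018, 0.015, "duct"),
#'   circ_section(0.12, 0.032, "tube 1")
#' ))
#' g$total_length
#' @export
tract_geometry <- function(sections) {
  if (!is.list(sections) || length(sections) < 1L)
    stop("invalid geometry: need at least one section", call. = FALSE)
  ok <- vapply(sections, inherits, logical(1), what = "tube_section")
  if (!all(ok))
    stop("invalid geometry: all elements must be `tube_section` objects", call. = FALSE)
  total <- sum(vapply(sections, `[[`, numeric(1), "length"))
  structure(list(sections = sections, total_length = total),
            class = "tract_geometry")
}

#' @export
print.tract_geometry <- function(x, ...) {
  cat(sprintf("Tract geometry: %d section(s), total length %.1f mm\n",
              length(x$sections), 1000 * x$total_length))
  for (s in x$sections) print(s)
  invisible(x)
}

#' Default geometry configuration for the telescoping vocal-tract replica
#'
#' Dimensions of the length-variable duct used throughout the package: a
#' rectangular supraglottal section directly downstream of the vocal folds,
#' followed by a first circular tube and a second, slightly wider circular
#' tube that telescopes over the first to set the total length.
#'
#' @param rect_length Length of the rectangular section, m.
#' @param rect_width,rect_height Rectangular cross-section, m.
#' @param tube1_diameter,tube2_diameter Diameters of the two circular tubes, m.
#' @param tube1_length Length taken by tube 1 before tube 2 contributes, m.
#'   The split of the remaining length between the two tubes is not fixed by
#'   the physical telescoping, so it is configurable; the default 0.120 m
#'   makes the shortest (200 mm) configuration use tube 1 only.
#'
#' @return A list of geometry parameters accepted by [build_geometry()].
#' @export
geometry_config <- function(rect_length = 0.080,
                            rect_width = 0.018, rect_height = 0.015,
                            tube1_diameter = 0.032, tube1_length = 0.120,
                            tube2_diameter = 0.034) {
  cfg <- list(rect_length = rect_length, rect_width = rect_width,
              rect_height = rect_height, tube1_diameter = tube1_diameter,
              tube1_length = tube1_length, tube2_diameter = tube2_diameter)
  bad <- names(cfg)[!vapply(cfg, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0, logical(1))]
  if (length(bad))
    stop("geometry config entries must be positive numbers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  cfg
}

#' Build the telescoping vocal-tract geometry for a total length
#'
#' Assembles the three-part duct: the rectangular supraglottal section, then
#' circular tube 1 up to its configured length, then circular tube 2 for the
#' remainder. Sections of zero length are dropped, so short tracts may have
#' one or two sections.
#'
#' @param L Total tract length in metres. Must be at least the rectangular
#'   section length (0.080 m by default).
#' @param config Geometry parameters from [geometry_config()].
#'
#' @return A [tract_geometry()] whose section lengths sum to `L`.
#' @examples
#' build_geometry(0.200) # rectangular duct + 120 mm of tube 1
#' build_geometry(0.800) # all three sections
#' @export
build_geometry <- function(L, config = geometry_config()) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L))
    stop("`L` must be a single number (metres)", call. = FALSE)
  tol <- 1e-12
  if (L < config$rect_length - tol)
    stop(sprintf("invalid geometry: L = %.4f m is below the %.3f m rectangular section",
                 L, config$rect_length), call. = FALSE)
  secs <- list(rect_section(config$rect_length, config$rect_width,
                            config$rect_height, "supraglottal duct"))
  rem <- L - config$rect_length
  l1 <- min(rem, config$tube1_length)
  if (l1 > tol)
    secs <- c(secs, list(circ_section(l1, config$tube1_diameter, "tube 1")))
  l2 <- rem - l1
  if (l2 > tol)
    secs <- c(secs, list(circ_section(l2, config$tube2_diameter, "tube 2")))
  g <- tract_geometry(secs)
  # guard against accumulation errors in the length bookkeeping
  stopifnot(abs(g$total_length - max(L, config$rect_length)) < 1e-9)
  g
}

#' Read or write a geometry as a structured text config
#'
#' Geometries are serialised as an ordered YAML list of segments with
#' dimensions in millimetres (`label`, `shape`, `length_mm`, and either
#' `width_mm`/`height_mm` or `diameter_mm`).
#'
#' @param geometry A [tract_geometry()].
#' @param path File path.
#' @return `write_geometry()` returns `path` invisibly; `read_geometry()`
#'   returns a [tract_geometry()].
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "tract_geometry"))
  segs <- lapply(geometry$sections, function(s) {
    out <- list(label = s$label, shape = s$shape, length_mm = 1000 * s$length)
    if (s$shape == "circular") {
      out$diameter_mm <- 2000 * sqrt(s$area / pi)
    } else {
      # serialised as a square of equal area unless the true aspect is known
      out$width_mm <- 1000 * sqrt(s$area)
      out$height_mm <- 1000 * sqrt(s$area)
    }
    out
  })
  yaml::write_yaml(list(segments = segs), path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$segments))
    stop("geometry config must contain a `segments` list", call. = FALSE)
  secs <- lapply(raw$segments, function(s) {
    if (identical(s$shape, "circular")) {
      circ_section(s$length_mm / 1000, s$diameter_mm / 1000, s$label %||% "")
    } else {
      rect_section(s$length_mm / 1000, s$width_mm / 1000, s$height_mm / 1000,
                   s$label %||% "")
    }
  })
  tract_geometry(secs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
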