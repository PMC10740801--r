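#' Write an acoustic signal as a 32-bit float WAV file
#'
#' Minimal RIFF/WAVE writer (IEEE float, mono). The calibrated Pa samples
#' are divided by the signal's calibration factor before writing, so the
#' file round-trips through [read_wav()] with the same calibration.
#'
#' @param sig An [acoustic_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(sig, path) {
  stopifnot(inherits(sig, "acoustic_signal"))
  samples <- sig$samples / sig$calibration
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  data_bytes <- 4L * n
  fs <- as.integer(round(sig$sample_rate))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")          # IEEE float
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * 4L), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(samples, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a 32-bit float mono WAV file
#'
#' @param path WAV file written by [write_wav()] (IEEE-float, mono).
#' @param calibration Pa per unit applied to the stored samples.
#' @return An [acoustic_signal()].
#' @export
read_wav <- function(path, calibration = 1) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE") stop("not a WAV file", call. = FALSE)
  fs <- NA_integer_; samples <- NULL; fmt <- NA_integer_
  repeat {
    id <- readChar(con, 4)
    if (!length(id) || !nzchar(id)) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), size = 2, endian = "little")
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, raw(), n = sz - 8L))
    } else if (id == "data") {
      if (fmt != 3L) stop("only IEEE-float WAV is supported", call. = FALSE)
      samples <- readBin(con, numeric(), n = sz %/% 4L, size = 4,
                         endian = "little")
      break
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
  }
  if (is.null(samples)) stop("no data chunk found", call. = FALSE)
  acoustic_signal(calibration * samples, fs, calibration)
}

#' Write or read a velocity-field series as long-format CSV
#'
#' Columns `t, x, y, u, v` (SI units), one row per sample. Intended for
#' interchange of moderate records; large series are better kept in
#' memory.
#'
#' @param field A `velocity_field_series`.
#' @param path File path.
#' @return `write_field_csv()` returns `path` invisibly;
#'   `read_field_csv()` returns a `velocity_field_series` (without the
#'   generating config).
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "velocity_field_series"))
  nt <- length(field$t); ny <- length(field$y); nx <- length(field$x)
  df <- data.frame(
    t = rep(field$t, times = ny * nx),
    x = rep(field$x, each = nt * ny),
    y = rep(rep(field$y, each = nt), times = nx),
    u = as.numeric(field$u),
    v = as.numeric(field$v)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  df <- utils::read.csv(path)
  t <- sort(unique(df$t)); x <- sort(unique(df$x)); y <- sort(unique(df$y))
  nt <- length(t); ny <- length(y); nx <- length(x)
  ord <- order(match(df$x, x), match(df$y, y), match(df$t, t))
  u <- array(df$u[ord], dim = c(nt, ny, nx))
  v <- array(df$v[ord], dim = c(nt, ny, nx))
  fs <- if (nt > 1L) 1 / (t[2L] - t[1L]) else NA_real_
  structure(list(x = x, y = y, t = t, u = u, v = v, sample_rate = fs,
                 config = NULL),
            class = "velocity_field_series")
}
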