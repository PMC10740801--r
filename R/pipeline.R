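#' Reference operating conditions for the length sweep
#'
#' The bundled table of benchmark operating points of the length-variable
#' vocal-tract experiment the package emulates: total supraglottal length
#' `L_mm`, minimum flow rate sustaining oscillation with glottis closure
#' `flow_lpm` (l/min), transglottal pressure `ptrans_pa` (Pa), vocal-fold
#' oscillation frequency `fo_hz` (Hz) and the first tract resonance
#' `fr1_hz` (Hz). These values seed the synthetic generators' per-length
#' defaults.
#'
#' @return A tibble with nine rows.
#' @export
sweep_conditions <- function() {
  path <- system.file("extdata", "length_sweep_conditions.csv",
                      package = "phonocouple", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path))
}

interp_condition <- function(tab, col, L_mm) {
  stats::approx(tab$L_mm, tab[[col]], xout = L_mm, rule = 2)$y
}

known_config_keys <- c("lengths_mm", "seed", "duration_s", "tube1_length_mm",
                       "constants", "flow", "acoustic", "observer_distance_m",
                       "per_length")

#' Load and validate a sweep run configuration
#'
#' Reads a YAML run configuration (or takes an equivalent named list) and
#' resolves defaults. The only required key is `lengths_mm`; per-length
#' operating points (`fo`, flow rate, transglottal pressure) default to the
#' bundled [sweep_conditions()] table, interpolated linearly in length.
#' Unknown keys are rejected.
#'
#' Recognised keys: `lengths_mm` (vector, each within 80-2000 mm), `seed`,
#' `duration_s` (velocity-record length per configuration), `tube1_length_mm`,
#' `constants` (`c0`, `rho0`), `flow` and `acoustic` (generator overrides
#' passed to [flow_config()] / [acoustic_config()]),
#' `observer_distance_m`, and `per_length` (a list keyed by length in mm
#' with entries `fo_hz`, `flow_lpm`, `ptrans_pa`).
#'
#' @param path Path to a YAML file, or a named list.
#' @return A validated `run_config` list with all defaults resolved.
#' @export
load_run_config <- function(path) {
  raw <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    tryCatch(yaml::read_yaml(path),
             error = function(e) stop("config error: malformed YAML in ", path,
                                      ": ", conditionMessage(e), call. = FALSE))
  } else if (is.list(path)) path
  else stop("config error: expected a file path or a named list", call. = FALSE)

  unknown <- setdiff(names(raw), known_config_keys)
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(raw$lengths_mm) || !length(raw$lengths_mm))
    stop("config error: `lengths_mm` is required", call. = FALSE)
  lengths <- as.numeric(raw$lengths_mm)
  if (any(!is.finite(lengths)) || any(lengths < 80) || any(lengths > 2000))
    stop("config error: lengths must lie within [80, 2000] mm", call. = FALSE)

  consts <- do.call(acoustic_constants, raw$constants %||% list())
  tab <- sweep_conditions()
  per_length <- lapply(lengths, function(L) {
    ov <- (raw$per_length %||% list())[[as.character(L)]] %||% list()
    bad <- setdiff(names(ov), c("fo_hz", "flow_lpm", "ptrans_pa"))
    if (length(bad))
      stop("config error: unknown per-length key(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    list(L_mm = L,
         fo_hz = ov$fo_hz %||% interp_condition(tab, "fo_hz", L),
         flow_lpm = ov$flow_lpm %||% interp_condition(tab, "flow_lpm", L),
         ptrans_pa = ov$ptrans_pa %||% interp_condition(tab, "ptrans_pa", L))
  })
  names(per_length) <- as.character(lengths)

  cfg <- list(lengths_mm = lengths,
              seed = as.integer(raw$seed %||% 1L),
              duration_s = raw$duration_s %||% 0.5,
              tube1_length_mm = raw$tube1_length_mm %||% 120,
              constants = consts,
              flow = raw$flow %||% list(),
              acoustic = raw$acoustic %||% list(),
              observer_distance_m = raw$observer_distance_m %||% 1,
              per_length = per_length)
  structure(cfg, class = "run_config")
}

#' Write a run configuration back to YAML
#'
#' @param cfg A `run_config` from [load_run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- unclass(cfg)
  out$constants <- list(c0 = cfg$constants$c0, rho0 = cfg$constants$rho0)
  out$per_length <- lapply(out$per_length, function(pl) pl[names(pl) != "L_mm"])
  yaml::write_yaml(out, path)
  invisible(path)
}

config_hash <- function(cfg) {
  out <- unclass(cfg)
  out$constants <- list(c0 = cfg$constants$c0, rho0 = cfg$constants$rho0)
  rlang::hash(out)
}

run_one_length <- function(cfg, i) {
  pl <- cfg$per_length[[i]]
  L <- pl$L_mm / 1000
  consts <- cfg$constants
  flow_rate <- pl$flow_lpm / 60000            # l/min -> m^3/s

  geom <- build_geometry(L, geometry_config(tube1_length = cfg$tube1_length_mm / 1000))
  sp <- impedance_spectrum(geom, consts = consts)
  fr1 <- find_resonances(sp)$resonances[1]

  fargs <- utils::modifyList(
    list(fo = pl$fo_hz, mean_flow_rate = flow_rate,
         duration = cfg$duration_s, seed = cfg$seed + i),
    cfg$flow)
  field <- generate_velocity_series(do.call(flow_config, fargs))
  duct_area <- field$config$duct_area

  src <- lighthill_source_field(field, consts)
  roi <- roi_from_field(src, observer_distance = cfg$observer_distance_m)
  sig <- summed_source_signal(src, roi, consts)
  Phi <- sig$Phi
  U <- flow_rate / duct_area
  P <- aerodynamic_input_power(pl$ptrans_pa, U, consts)
  eta <- aeroacoustic_efficiency(Phi, roi, P, consts)

  vspec <- averaged_velocity_psd(field)
  fo_extracted <- extract_fundamental(vspec)

  aargs <- utils::modifyList(
    list(fo = pl$fo_hz, duration = cfg$duration_s, seed = cfg$seed + 1000L + i),
    cfg$acoustic)
  audio <- generate_acoustic_signal(do.call(acoustic_config, aargs))
  sh <- snr_hnr(audio, fo = pl$fo_hz)
  cp <- cpp(audio)
  p_rms <- sqrt(mean(audio$samples^2))
  ve <- vocal_efficiency(p_rms, cfg$observer_distance_m, pl$ptrans_pa, flow_rate,
                         consts)

  list(row = tibble::tibble(
    L_mm = pl$L_mm, fR1_Hz = fr1, fo_Hz = pl$fo_hz,
    fo_extracted_Hz = fo_extracted, U_mps = U, Phi = Phi, P_Pa = P,
    eta = eta, eta_theor = NA_real_, SPL_dB = spl(audio), VE = ve,
    SNR_dB = sh$snr_db, HNR_dB = sh$hnr_db, CPP_dB = cp$cpp_db,
    status = "ok"),
    detail = list(spectrum = sp, velocity_psd = vspec, source_signal = sig,
                  audio = audio))
}

#' Run the vocal-tract length sweep
#'
#' For each configured length: builds the tract geometry and extracts its
#' first resonance; generates a seeded synthetic velocity-field series at
#' the length's operating point; computes the Lighthill source field, the
#' aggregated source signal, its RMS `Phi`, the input pressure `P` and the
#' efficiency `eta` (with the fifth-power prediction `eta_theor` anchored
#' at the smallest length); generates a synthetic microphone signal and
#' computes SPL, SNR, HNR, CPP and vocal efficiency. Failures in one
#' length are recorded in its row and do not stop the sweep.
#'
#' @param cfg A `run_config` from [load_run_config()].
#' @param keep_details Keep per-length spectra, source signals and audio in
#'   the result (default TRUE).
#' @return A `run_report`: list with `summary` (tibble, one row per
#'   length), `details`, and `provenance` (seed, config hash, package
#'   version).
#' @export
run_sweep <- function(cfg, keep_details = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  n <- length(cfg$lengths_mm)
  rows <- vector("list", n)
  details <- vector("list", n)
  for (i in seq_len(n)) {
    res <- tryCatch(run_one_length(cfg, i), error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- tibble::tibble(
        L_mm = cfg$lengths_mm[i], fR1_Hz = NA_real_, fo_Hz = NA_real_,
        fo_extracted_Hz = NA_real_, U_mps = NA_real_, Phi = NA_real_,
        P_Pa = NA_real_, eta = NA_real_, eta_theor = NA_real_,
        SPL_dB = NA_real_, VE = NA_real_, SNR_dB = NA_real_,
        HNR_dB = NA_real_, CPP_dB = NA_real_,
        status = paste("error:", conditionMessage(res)))
    } else {
      rows[[i]] <- res$row
      if (keep_details) details[[i]] <- res$detail
    }
  }
  summary <- do.call(rbind, rows)
  # fifth-power prediction anchored at the smallest length's measured point
  ok <- summary$status == "ok"
  if (any(ok)) {
    anchor <- which(ok)[which.min(summary$L_mm[ok])]
    summary$eta_theor <- mach_fifth_power_prediction(
      summary$eta[anchor], summary$U_mps[anchor], summary$U_mps)
  }
  names(details) <- as.character(cfg$lengths_mm)
  structure(list(summary = summary, details = details,
                 provenance = list(seed = cfg$seed,
                                   config_hash = config_hash(cfg),
                                   package_version =
                                     as.character(utils::packageVersion("phonocouple")))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Length-sweep report (seed", x$provenance$seed, ")\n")
  print(x$summary)
  invisible(x)
}

#' Export a sweep report to files
#'
#' Writes `summary.csv`, a `manifest.json` (seed, config hash, package
#' version, row count), and, where details were kept, per-length
#' `phi_L<mm>.csv` source signals, `spectrum_L<mm>.csv` impedance spectra,
#' `velocity_psd_L<mm>.csv` spectra and `audio_L<mm>.wav` files. All
#' outputs are deterministic functions of the report, so re-export is
#' idempotent.
#'
#' @param report A `run_report` from [run_sweep()].
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
export_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  p <- file.path(dir, "summary.csv")
  utils::write.csv(report$summary, p, row.names = FALSE, quote = FALSE)
  written <- c(written, p)
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(c(report$provenance,
                         list(n_rows = nrow(report$summary))),
                       p, auto_unbox = TRUE, pretty = TRUE)
  written <- c(written, p)
  for (nm in names(report$details)) {
    d <- report$details[[nm]]
    if (is.null(d)) next
    p <- file.path(dir, sprintf("phi_L%s.csv", nm))
    utils::write.csv(data.frame(t = d$source_signal$t, phi = d$source_signal$phi),
                     p, row.names = FALSE, quote = FALSE)
    written <- c(written, p)
    p <- file.path(dir, sprintf("spectrum_L%s.csv", nm))
    utils::write.csv(data.frame(f_Hz = d$spectrum$frequencies,
                                Zin_abs = abs(d$spectrum$Zin)),
                     p, row.names = FALSE, quote = FALSE)
    written <- c(written, p)
    p <- file.path(dir, sprintf("velocity_psd_L%s.csv", nm))
    utils::write.csv(data.frame(f_Hz = d$velocity_psd$frequencies,
                                psd = d$velocity_psd$psd),
                     p, row.names = FALSE, quote = FALSE)
    written <- c(written, p)
    p <- file.path(dir, sprintf("audio_L%s.wav", nm))
    write_wav(d$audio, p)
    written <- c(written, p)
  }
  invisible(written)
}
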