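.TRANSIENT_FORMAT_VERSION <- "1.0"

# Serialize/deserialize the truth record embedded in a transient container.
#' @noRd
truth_to_json <- function(truth) {
  if (is.null(truth)) return(NULL)
  list(
    noise_sigma = truth$noise_sigma,
    ions = lapply(truth$ions, function(ti) {
      if (is.null(ti$spec)) return(ti)   # already in serialized form
      sp <- ti$spec
      list(mass = sp$mass, charge = sp$charge, phase0 = sp$phase0,
           charge_loss_time = sp$charge_loss_time,
           radial_freq = sp$radial_freq, radial_depth = sp$radial_depth,
           amp_scale = sp$amp_scale,
           mz0 = ti$mz0, f0 = ti$f0, final_mass = ti$final_mass,
           final_charge = ti$final_charge, final_mz = ti$final_mz,
           event_times = ti$events$time, event_masses = ti$events$mass)
    }))
}

#' Write a transient container
#'
#' Open on-disk format for raw transients: the samples as a little-endian
#' 32-bit float block at `path`, and a JSON metadata sidecar at
#' `<path>.json` (format version, sampling parameters, seed and the
#' optional generating-truth record). Samples are quantized to 32-bit
#' floats on write; a written container round-trips bit-exactly.
#'
#' @param transient A `transient` with finite samples.
#' @param path Output path for the sample block.
#' @return `path`, invisibly.
#' @export
write_transient <- function(transient, path) {
  if (any(!is.finite(transient$samples)))
    abort_invalid("refusing to write non-finite samples")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(transient$samples), con, size = 4L,
           endian = "little")
  meta <- list(format_version = .TRANSIENT_FORMAT_VERSION,
               sample_rate_hz = transient$sample_rate,
               duration_s = transient$duration,
               n_samples = transient$n_samples,
               seed = transient$seed,
               truth = truth_to_json(transient$truth))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a transient container
#'
#' Validates the format version and the declared sample count against the
#' file size before reading; truncated or foreign files are refused with an
#' explicit message.
#'
#' @param path Path to the sample block written by [write_transient()].
#' @return A `transient`; any truth record is restored under `$truth` in
#'   list form.
#' @export
read_transient <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(meta_path))
    abort_invalid("missing transient container at ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  if (!identical(meta$format_version, .TRANSIENT_FORMAT_VERSION))
    abort_invalid("unsupported format_version '", meta$format_version,
                  "' (expected ", .TRANSIENT_FORMAT_VERSION, ")")
  found <- file.size(path) / 4
  if (found != meta$n_samples)
    abort_invalid("truncated sample block: expected ", meta$n_samples,
                  " samples, found ", found)
  con <- file(path, "rb")
  on.exit(close(con))
  samples <- readBin(con, numeric(), n = meta$n_samples, size = 4L,
                     endian = "little")
  if (any(!is.finite(samples)))
    abort_invalid("sample block contains non-finite values")
  tr <- new_transient(samples, meta$sample_rate_hz,
                      seed = meta$seed %||% NA_integer_)
  tr$truth <- meta$truth
  tr
}

#' Write / read centroid tables
#'
#' CSV with columns `scan_id`, `segment_index`, `mz`, `frequency_hz`,
#' `intensity`, `fwhm_th`, `snr` (UTF-8, '.' decimal separator).
#'
#' @param centroids Centroid data.frame.
#' @param path File path.
#' @param scan_id Scan identifier recorded with each row.
#' @return `path` invisibly (write); the data.frame (read).
#' @export
write_centroids <- function(centroids, path, scan_id = 1L) {
  df <- data.frame(scan_id = scan_id,
                   segment_index = centroids$segment_index,
                   mz = centroids$mz, frequency_hz = centroids$frequency_hz,
                   intensity = centroids$intensity,
                   fwhm_th = centroids$fwhm_th, snr = centroids$snr)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centroids
#' @export
read_centroids <- function(path) utils::read.csv(path)

#' Write / read trace tables
#'
#' CSV with columns `trace_id`, `scan_id`, `segment_index`, `mz`,
#' `intensity`, `classification`, `assigned_charge`.
#'
#' @param traces List of `ion_trace` objects.
#' @param path File path.
#' @param scan_id Scan identifier.
#' @return `path` invisibly (write); the data.frame (read).
#' @export
write_traces <- function(traces, path, scan_id = 1L) {
  rows <- lapply(traces, function(tr)
    data.frame(trace_id = tr$trace_id, scan_id = scan_id,
               segment_index = tr$centroids$segment_index,
               mz = tr$centroids$mz, intensity = tr$centroids$intensity,
               classification = tr$classification %||% NA_character_,
               assigned_charge = tr$assigned_charge))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trace_id = integer(0), scan_id = integer(0),
               segment_index = integer(0), mz = numeric(0),
               intensity = numeric(0), classification = character(0),
               assigned_charge = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) utils::read.csv(path)

#' Write / read CDMS ion tables
#'
#' CSV with columns `scan_id`, `trace_id`, `mz`, `intensity`, `charge`,
#' `charge_int`, `mass`, `source`, `flags`.
#'
#' @param ions CDMS ion data.frame.
#' @param path File path.
#' @param scan_id Scan identifier (recycled).
#' @return `path` invisibly (write); the data.frame (read).
#' @export
write_ions <- function(ions, path, scan_id = 1L) {
  df <- cbind(scan_id = scan_id, ions)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ions
#' @export
read_ions <- function(path) utils::read.csv(path)

#' Write a mass histogram as CSV
#'
#' Columns `bin_low`, `bin_high`, `count`.
#'
#' @param histogram A `mass_histogram`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(histogram, path) {
  nb <- length(histogram$counts)
  utils::write.csv(
    data.frame(bin_low = histogram$breaks[seq_len(nb)],
               bin_high = histogram$breaks[seq_len(nb) + 1],
               count = histogram$counts),
    path, row.names = FALSE)
  invisible(path)
}

#' Read / write flat key-value configuration
#'
#' Text format: one `dotted.key = value` per line, `#` comments. Keys in
#' the `instrument.` and `gas.` namespaces map onto [instrument_model()]
#' and [gas_model()] fields; [config_instrument()] and [config_gas()] build
#' the models, applying the named pressure preset when `gas.pressure_preset`
#' is set.
#'
#' @param path File path.
#' @return Named list of values (numeric where possible).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_invalid("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      abort_invalid("malformed config line: '", ln, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' @rdname read_config
#' @param config Named list from [read_config()].
#' @export
config_instrument <- function(config) {
  take <- function(key, default) config[[paste0("instrument.", key)]] %||%
    default
  instrument_model(
    freq_coeff = take("freq_coeff", 0.26055),
    dist_per_osc = take("dist_per_osc", 93.7425),
    sample_rate = take("sample_rate", 250000),
    zero_pad_factor = take("zero_pad_factor", 4),
    charge_gain = take("charge_gain", 175),
    proton_mass = take("proton_mass", 1.00728))
}

#' @rdname read_config
#' @export
config_gas <- function(config) {
  take <- function(key) config[[paste0("gas.", key)]]
  pressure <- take("gauge_pressure")
  preset <- take("pressure_preset")
  if (!is.null(preset)) {
    presets <- pressure_presets()
    if (!preset %in% names(presets))
      abort_invalid("unknown pressure preset '", preset, "'")
    pressure <- unname(presets[preset])
  }
  gas_model(
    species = take("species") %||% "nitrogen",
    gas_mass = take("gas_mass"), gas_radius = take("gas_radius"),
    gauge_pressure = pressure %||% 2.6e-10,
    trap_pressure_multiplier = take("trap_pressure_multiplier") %||% 2,
    gauge_gas_correction = take("gauge_gas_correction"),
    temperature = take("temperature") %||% 298.15)
}
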