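#' Instrument model: frequency law, geometry and charge calibration
#'
#' Bundles the constants that tie an Orbitrap image-current transient to
#' physical ion properties: the axial frequency law
#' \eqn{f = c \times (m/z \times 10^{-3})^{-1/2}} (MHz, with `freq_coeff`
#' \eqn{c} calibrated for m/z expressed in kilothomson), the average distance
#' an ion travels per axial oscillation, the digitizer rate, the zero-padding
#' factor used for spectral processing and the factor converting normalized
#' magnitude-spectrum peak height into elementary charges.
#'
#' @param freq_coeff Frequency-law coefficient in MHz at m/z = 1,000 Th.
#' @param dist_per_osc Average travelled distance per axial oscillation, mm.
#' @param sample_rate Digitizer sampling rate, Hz. The default 250 kHz covers
#'   all axial frequencies for m/z > ~4,350 Th; a full-rate instrument mode
#'   would use 4 MHz.
#' @param zero_pad_factor Integer zero-padding factor applied before the FFT.
#' @param charge_gain Charges per unit normalized spectral intensity.
#' @param proton_mass Proton mass in Da.
#' @return An object of class `instrument_model`.
#' @examples
#' model <- instrument_model()
#' mz_to_freq(1000, model)  # 260,550 Hz by definition of the coefficient
#' @export
instrument_model <- function(freq_coeff = 0.26055,
                             dist_per_osc = 93.7425,
                             sample_rate = 250000,
                             zero_pad_factor = 4L,
                             charge_gain = 175,
                             proton_mass = 1.00728) {
  check_number(freq_coeff, "freq_coeff")
  check_number(dist_per_osc, "dist_per_osc")
  check_number(sample_rate, "sample_rate")
  check_number(zero_pad_factor, "zero_pad_factor")
  if (zero_pad_factor < 1 || zero_pad_factor != round(zero_pad_factor))
    abort_invalid("zero_pad_factor must be an integer >= 1")
  check_number(charge_gain, "charge_gain")
  check_number(proton_mass, "proton_mass")
  structure(
    list(freq_coeff = freq_coeff, dist_per_osc = dist_per_osc,
         sample_rate = sample_rate, zero_pad_factor = as.integer(zero_pad_factor),
         charge_gain = charge_gain, proton_mass = proton_mass),
    class = "instrument_model")
}

#' @export
print.instrument_model <- function(x, ...) {
  cat("<instrument_model>\n")
  cat(sprintf("  frequency law : f = %.5f MHz x (m/z / 1000 Th)^-1/2\n",
              x$freq_coeff))
  cat(sprintf("  dist/osc      : %.4f mm\n", x$dist_per_osc))
  cat(sprintf("  sampling      : %g Hz, zero-pad x%d\n",
              x$sample_rate, x$zero_pad_factor))
  cat(sprintf("  charge gain   : %g charges per unit intensity\n",
              x$charge_gain))
  invisible(x)
}

#' Background-gas model for collision estimates
#'
#' Describes the neutral gas in the analyser region: its mass and hard-sphere
#' radius, the ultra-high-vacuum cold-cathode gauge read-out, the multiplier
#' accounting for the true trap pressure exceeding the gauge read-out
#' (approximately twofold), and the gauge sensitivity correction for gases
#' other than the nitrogen the gauge is calibrated for.
#'
#' For `species = "xenon"` the defaults switch to xenon's mass/radius and the
#' gauge read-out is divided by a relative sensitivity of 2.4
#' (`gauge_gas_correction = 1/2.4`); any field can still be overridden.
#'
#' @param species `"nitrogen"` or `"xenon"` (sets mass/radius/correction
#'   defaults), or any other label if all fields are supplied.
#' @param gas_mass Gas molecular mass, Da.
#' @param gas_radius Hard-sphere gas radius, m.
#' @param gauge_pressure Cold-cathode gauge read-out, mbar. Presets
#'   `pressure_presets()` give the low/high read-outs 2.6e-10 and 8e-10 mbar.
#' @param trap_pressure_multiplier True trap pressure over gauge read-out.
#' @param gauge_gas_correction Relative gauge sensitivity correction
#'   (1 for nitrogen).
#' @param temperature Gas temperature, K (default 25 degrees C).
#' @return An object of class `gas_model`.
#' @examples
#' gas_model("xenon", gauge_pressure = pressure_presets()[["low_pressure"]])
#' @export
gas_model <- function(species = "nitrogen",
                      gas_mass = NULL, gas_radius = NULL,
                      gauge_pressure = 2.6e-10,
                      trap_pressure_multiplier = 2,
                      gauge_gas_correction = NULL,
                      temperature = 298.15) {
  defaults <- switch(species,
    nitrogen = list(mass = 28.014, radius = 1.82e-10, corr = 1),
    xenon    = list(mass = 131.293, radius = 2.16e-10, corr = 1 / 2.4),
    list(mass = NULL, radius = NULL, corr = 1))
  gas_mass <- gas_mass %||% defaults$mass
  gas_radius <- gas_radius %||% defaults$radius
  gauge_gas_correction <- gauge_gas_correction %||% defaults$corr
  if (is.null(gas_mass) || is.null(gas_radius))
    abort_invalid("gas_mass and gas_radius are required for species '",
                  species, "'")
  check_number(gas_mass, "gas_mass")
  check_number(gas_radius, "gas_radius")
  check_number(gauge_pressure, "gauge_pressure")
  check_number(trap_pressure_multiplier, "trap_pressure_multiplier")
  if (trap_pressure_multiplier < 1)
    abort_invalid("trap_pressure_multiplier must be >= 1")
  check_number(gauge_gas_correction, "gauge_gas_correction")
  check_number(temperature, "temperature")
  structure(
    list(species = species, gas_mass = gas_mass, gas_radius = gas_radius,
         gauge_pressure = gauge_pressure,
         trap_pressure_multiplier = trap_pressure_multiplier,
         gauge_gas_correction = gauge_gas_correction,
         temperature = temperature),
    class = "gas_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gas_model <- function(x, ...) {
  cat(sprintf("<gas_model> %s: %.3f Da, r = %.3g m\n",
              x$species, x$gas_mass, x$gas_radius))
  cat(sprintf("  gauge %.3g mbar x %.2g (trap) x %.3g (gauge corr), %g K\n",
              x$gauge_pressure, x$trap_pressure_multiplier,
              x$gauge_gas_correction, x$temperature))
  invisible(x)
}

#' Standard ultra-high-vacuum gauge read-outs
#'
#' The two cold-cathode gauge read-outs used as low/high pressure operating
#' points, in mbar.
#' @return Named numeric vector with `low_pressure` and `high_pressure`.
#' @export
pressure_presets <- function() {
  c(low_pressure = 2.6e-10, high_pressure = 8e-10)
}

#' Convert m/z to axial oscillation frequency
#'
#' Applies the instrument frequency law
#' \eqn{f = c \cdot 10^6 \times (m/z / 1000)^{-1/2}} Hz.
#'
#' @param mz m/z in thomson; vectorized.
#' @param model An [instrument_model()].
#' @return Axial frequency in Hz.
#' @examples
#' mz_to_freq(21343.1)  # ~56.4 kHz
#' @export
mz_to_freq <- function(mz, model = instrument_model()) {
  check_number(mz, "mz", scalar = FALSE)
  model$freq_coeff * 1e6 * (mz / 1000)^(-0.5)
}

#' Convert axial frequency to m/z
#'
#' Inverse of [mz_to_freq()]: \eqn{m/z = 1000 (c \cdot 10^6 / f)^2}.
#'
#' @param f Frequency in Hz; vectorized.
#' @param model An [instrument_model()].
#' @return m/z in thomson.
#' @export
freq_to_mz <- function(f, model = instrument_model()) {
  check_number(f, "f", scalar = FALSE)
  1000 * (model$freq_coeff * 1e6 / f)^2
}

#' Ion path length during a transient
#'
#' Product of transient duration, axial frequency and average travelled
#' distance per oscillation. A megadalton ion at m/z ~21,000 covers more than
#' 5 km per second of detection.
#'
#' @param mz m/z in thomson.
#' @param duration Transient duration, s.
#' @param model An [instrument_model()].
#' @return Path length in metres.
#' @examples
#' path_length(21343.1, 1)       # ~5.29 km
#' path_length(21343.1, 4.096)   # > 20 km
#' @export
path_length <- function(mz, duration, model = instrument_model()) {
  check_number(mz, "mz", scalar = FALSE)
  check_number(duration, "duration")
  duration * mz_to_freq(mz, model) * model$dist_per_osc / 1000
}
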