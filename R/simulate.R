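#' Specify a single ion for transient simulation
#'
#' @param mass Ionic mass, Da (m/z = mass / charge).
#' @param charge Charge state, positive integer.
#' @param phase0 Initial oscillation phase, rad.
#' @param loss Optional [loss_process()] driving gradual neutral loss.
#' @param charge_loss_time Optional time (s) of a single charge-stripping
#'   event; the ion continues at charge - 1.
#' @param charge_loss_carries_proton If TRUE (default) the departing charge
#'   removes one proton mass; if FALSE the mass is strictly conserved.
#' @param radial_freq Optional radial modulation frequency, Hz; imposes
#'   amplitude modulation producing mirrored sidebands around the axial peak.
#' @param radial_depth Modulation depth in `[0, 1)`.
#' @param radial_phase Modulation phase, rad.
#' @param amp_scale Optional per-ion amplitude scale factor (default 1),
#'   standing in for the spread of accepted ion energies.
#' @return An object of class `ion_spec`.
#' @export
ion_spec <- function(mass, charge, phase0 = 0, loss = NULL,
                     charge_loss_time = NULL,
                     charge_loss_carries_proton = TRUE,
                     radial_freq = NULL, radial_depth = 0,
                     radial_phase = 0, amp_scale = 1) {
  check_number(mass, "mass")
  check_number(charge, "charge")
  if (charge < 1 || charge != round(charge))
    abort_invalid("charge must be a positive integer")
  if (!is.null(charge_loss_time)) check_number(charge_loss_time,
                                               "charge_loss_time")
  if (!is.null(radial_freq)) check_number(radial_freq, "radial_freq")
  check_number(radial_depth, "radial_depth", allow_zero = TRUE)
  if (radial_depth >= 1) abort_invalid("radial_depth must be < 1")
  check_number(amp_scale, "amp_scale")
  if (!is.null(loss) && !inherits(loss, "loss_process"))
    abort_invalid("loss must be a loss_process")
  structure(
    list(mass = mass, charge = as.integer(charge), phase0 = phase0,
         loss = loss, charge_loss_time = charge_loss_time,
         charge_loss_carries_proton = charge_loss_carries_proton,
         radial_freq = radial_freq, radial_depth = radial_depth,
         radial_phase = radial_phase, amp_scale = amp_scale),
    class = "ion_spec")
}

#' @noRd
new_transient <- function(samples, sample_rate, seed = NA_integer_,
                          truth = NULL) {
  if (any(!is.finite(samples)))
    abort_invalid("transient samples must be finite")
  structure(
    list(samples = samples, sample_rate = sample_rate,
         duration = length(samples) / sample_rate,
         n_samples = length(samples), seed = seed, truth = truth),
    class = "transient")
}

#' @export
print.transient <- function(x, ...) {
  cat(sprintf("<transient> %d samples @ %g Hz (%.4g s), seed %s, %d ion(s)\n",
              x$n_samples, x$sample_rate, x$duration,
              ifelse(is.na(x$seed), "-", x$seed),
              length(x$truth$ions)))
  invisible(x)
}

# Draw neutral-loss event times/masses for one ion over [0, duration]
#' @noRd
draw_loss_events <- function(loss, duration) {
  total_expect <- loss_cumulative_da(loss, duration)
  if (total_expect <= 0)
    return(data.frame(time = numeric(0), mass = numeric(0)))
  if (!loss$stochastic) return(NULL)  # handled as continuous mean drift
  k <- stats::rpois(1, total_expect / loss$loss_mass_mean)
  if (k == 0) return(data.frame(time = numeric(0), mass = numeric(0)))
  grid <- seq(0, duration, length.out = 2048)
  cum <- loss_cumulative_da(loss, grid) / total_expect
  times <- sort(stats::approx(cum, grid, xout = stats::runif(k),
                              ties = "ordered")$y)
  masses <- pmax(stats::rnorm(k, loss$loss_mass_mean, loss$loss_mass_sd), 0)
  data.frame(time = times, mass = masses)
}

#' Simulate a single-ion image-current transient
#'
#' Synthesizes the real-valued detector signal of one or more trapped ions:
#' each ion contributes \eqn{a_i(t)\cos\phi_i(t)} with instantaneous
#' frequency given by the instrument law at its current m/z, phase continuous
#' through all loss events. Neutral-loss events lower the mass (frequency
#' rises); a charge-stripping event multiplies the amplitude by (z-1)/z and
#' moves the ion to m/z = mass/(z-1) (frequency falls). Radial motion is
#' modelled as amplitude modulation. Amplitudes are calibrated so a
#' non-decaying ion's normalized spectral peak height equals
#' charge / charge_gain, i.e. [intensity_to_charge()] returns the true
#' charge. White Gaussian noise of SD `noise_sigma` is added.
#'
#' The default `noise_sigma` of 2 puts a z = 150 megadalton ion at a spectral
#' signal-to-noise ratio of roughly 400 over a 4 s transient.
#'
#' @param ions List of [ion_spec()] objects (possibly empty: noise only).
#' @param model An [instrument_model()].
#' @param noise_sigma Time-domain white-noise SD (same units as the signal).
#' @param duration Transient duration, s.
#' @param seed Integer RNG seed; identical inputs and seed give identical
#'   samples.
#' @param sample_rate Sampling rate, Hz (default from `model`).
#' @param keep_truth Record the generating specs and event times in
#'   `$truth` (default TRUE).
#' @return A `transient` object.
#' @examples
#' tr <- simulate_transient(list(ion_spec(3.2e6, 150)), noise_sigma = 0,
#'                          duration = 0.25, seed = 1)
#' @export
simulate_transient <- function(ions = list(), model = instrument_model(),
                               noise_sigma = 2, duration = 1, seed = 1,
                               sample_rate = model$sample_rate,
                               keep_truth = TRUE) {
  check_number(duration, "duration")
  check_number(noise_sigma, "noise_sigma", allow_zero = TRUE)
  if (inherits(ions, "ion_spec")) ions <- list(ions)
  n <- round(sample_rate * duration)
  if (n < 2) abort_invalid("duration too short for the sample rate")
  set.seed(seed)
  t <- (seq_len(n) - 1) / sample_rate
  samples <- numeric(n)
  truth_ions <- vector("list", length(ions))
  for (j in seq_along(ions)) {
    ion <- ions[[j]]
    if (!inherits(ion, "ion_spec")) abort_invalid("ions must be ion_spec")
    if (!is.null(ion$charge_loss_time) &&
        (ion$charge_loss_time <= 0 || ion$charge_loss_time >= duration))
      abort_invalid("charge_loss_time must lie within (0, duration)")
    # mass path from neutral losses
    mass_t <- rep(ion$mass, n)
    events <- NULL
    if (!is.null(ion$loss)) {
      events <- draw_loss_events(ion$loss, duration)
      if (is.null(events)) {           # deterministic mean drift
        mass_t <- ion$mass - loss_cumulative_da(ion$loss, t)
      } else if (nrow(events) > 0) {
        cum <- c(0, cumsum(events$mass))
        mass_t <- ion$mass - cum[findInterval(t, events$time) + 1]
      }
    }
    # charge path (single optional stripping event)
    z_t <- rep(as.numeric(ion$charge), n)
    if (!is.null(ion$charge_loss_time)) {
      after <- t >= ion$charge_loss_time
      z_t[after] <- ion$charge - 1
      if (ion$charge_loss_carries_proton)
        mass_t[after] <- mass_t[after] - model$proton_mass
    }
    freq <- mz_to_freq(mass_t / z_t, model)
    if (max(freq) >= sample_rate / 2)
      abort_invalid(sprintf(
        "Nyquist violation: ion frequency %.0f Hz >= sample_rate/2 (%.0f Hz)",
        max(freq), sample_rate / 2))
    phase <- ion$phase0 + 2 * pi * (cumsum(freq) - freq) / sample_rate
    amp <- (z_t / model$charge_gain) * ion$amp_scale
    if (!is.null(ion$radial_freq) && ion$radial_depth > 0)
      amp <- amp * (1 + ion$radial_depth *
                      cos(2 * pi * ion$radial_freq * t + ion$radial_phase))
    samples <- samples + amp * cos(phase)
    if (keep_truth)
      truth_ions[[j]] <- list(
        spec = ion, mz0 = ion$mass / ion$charge,
        f0 = mz_to_freq(ion$mass / ion$charge, model),
        final_mass = mass_t[n], final_charge = z_t[n],
        final_mz = mass_t[n] / z_t[n],
        events = if (is.null(events))
          data.frame(time = numeric(0), mass = numeric(0)) else events)
  }
  if (noise_sigma > 0)
    samples <- samples + stats::rnorm(n, 0, noise_sigma)
  new_transient(samples, sample_rate, seed = seed,
                truth = if (keep_truth)
                  list(ions = truth_ions, noise_sigma = noise_sigma,
                       model = model) else NULL)
}

#' Simulate an ensemble of single-ion scans
#'
#' Generates a reproducible population of transients emulating a CDMS
#' acquisition: `n_ions` true masses are drawn from one or more Gaussian
#' modes, charges follow \eqn{z = round(c\, m^e)} (Rayleigh-like charging,
#' c = 0.078, e = 0.5 by default), and ions are distributed over scans with
#' Poisson-distributed occupancy.
#'
#' The `"hbv"` preset draws an equal mixture of ~3 MDa and ~4 MDa particles
#' (icosahedral T=3/T=4 capsid masses).
#'
#' @param n_ions Total number of ions (>= 1).
#' @param mass_mean,mass_sd Mode means and SDs, Da (vectors for mixtures).
#' @param mode_weights Mixture weights (default equal).
#' @param preset Optional preset name (`"hbv"`) overriding the mass modes.
#' @param charge_coef,charge_exponent Charge-law parameters.
#' @param loss Optional [loss_process()] applied to every ion.
#' @param mean_ions_per_scan Poisson mean occupancy per scan (default 5).
#' @param noise_sigma,duration,model,sample_rate As [simulate_transient()].
#' @param phase_random Randomize initial phases (default TRUE).
#' @param seed Integer RNG seed.
#' @return List of `transient` objects; ion truth records are embedded.
#' @export
simulate_population <- function(n_ions, mass_mean = 4e6, mass_sd = 1.5e4,
                                mode_weights = NULL, preset = NULL,
                                charge_coef = 0.078, charge_exponent = 0.5,
                                loss = NULL, mean_ions_per_scan = 5,
                                noise_sigma = 2, duration = 1,
                                model = instrument_model(),
                                sample_rate = model$sample_rate,
                                phase_random = TRUE, seed = 1) {
  check_number(n_ions, "n_ions")
  if (n_ions < 1) abort_invalid("n_ions must be >= 1")
  if (!is.null(preset)) {
    if (preset == "hbv") {
      mass_mean <- c(3e6, 4e6); mass_sd <- c(1.5e4, 1.5e4)
    } else abort_invalid("unknown preset '", preset, "'")
  }
  check_number(mass_mean, "mass_mean", scalar = FALSE)
  check_number(mass_sd, "mass_sd", scalar = FALSE, allow_zero = TRUE)
  if (length(mass_sd) == 1) mass_sd <- rep(mass_sd, length(mass_mean))
  if (length(mass_sd) != length(mass_mean))
    abort_invalid("mass_sd must match mass_mean in length")
  weights <- mode_weights %||% rep(1, length(mass_mean))
  if (length(weights) != length(mass_mean) || any(weights < 0) ||
      sum(weights) <= 0)
    abort_invalid("invalid mode_weights")
  set.seed(seed)
  modes <- sample.int(length(mass_mean), n_ions, replace = TRUE,
                      prob = weights / sum(weights))
  masses <- stats::rnorm(n_ions, mass_mean[modes], mass_sd[modes])
  charges <- pmax(1, round(charge_coef * masses^charge_exponent))
  phases <- if (phase_random) stats::runif(n_ions, 0, 2 * pi) else
    rep(0, n_ions)
  # assign ions to scans with Poisson occupancy
  scan_of <- integer(n_ions); scan <- 0L; left <- n_ions; i <- 1L
  while (left > 0) {
    scan <- scan + 1L
    k <- min(stats::rpois(1, mean_ions_per_scan), left)
    if (k > 0) { scan_of[i:(i + k - 1)] <- scan; i <- i + k; left <- left - k }
  }
  scan_seeds <- abs(seed %% 1000L) * 1000000L + seq_len(scan)
  out <- vector("list", scan)
  for (s in seq_len(scan)) {
    idx <- which(scan_of == s)
    ions <- lapply(idx, function(i)
      ion_spec(masses[i], charges[i], phase0 = phases[i], loss = loss))
    out[[s]] <- simulate_transient(ions, model = model,
                                   noise_sigma = noise_sigma,
                                   duration = duration,
                                   seed = scan_seeds[s],
                                   sample_rate = sample_rate)
  }
  out
}
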