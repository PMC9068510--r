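#' Hard-sphere collision cross-section from radii
#'
#' \eqn{CCS = \pi (r_i + r_n)^2}; for megadalton particles the neutral-gas
#' radius is negligible and the CCS reduces to \eqn{\pi r_i^2}.
#'
#' @param ion_radius Ion radius, m.
#' @param gas_radius Neutral gas radius, m (default 0).
#' @return Cross-section in m^2.
#' @examples
#' ccs_from_radius(18e-9)  # ~1.02e-15 m^2 for a ~36 nm diameter capsid
#' @export
ccs_from_radius <- function(ion_radius, gas_radius = 0) {
  check_number(ion_radius, "ion_radius", allow_zero = TRUE, scalar = FALSE)
  check_number(gas_radius, "gas_radius", allow_zero = TRUE)
  pi * (ion_radius + gas_radius)^2
}

#' Gas number density in the trap
#'
#' Ideal-gas number density from the cold-cathode gauge read-out, after
#' applying the trap-pressure multiplier and the gauge gas-sensitivity
#' correction: \eqn{n = p / (k_B T)} with p in Pa (1 mbar = 100 Pa exactly).
#'
#' @param gas A [gas_model()].
#' @return Number density in m^-3.
#' @export
number_density <- function(gas) {
  check_number(gas$gauge_pressure, "gauge_pressure")
  check_number(gas$temperature, "temperature")
  p_pa <- gas$gauge_pressure * gas$trap_pressure_multiplier *
    gas$gauge_gas_correction * .MBAR_TO_PA
  p_pa / (.kB * gas$temperature)
}

#' Expected ion-gas collisions over a transient
#'
#' Combines path length, hard-sphere CCS and gas number density: the mean
#' free path is \eqn{1/(n \times CCS)} and the expected number of collisions
#' the quotient of travelled distance and mean free path. Exactly linear in
#' duration and in gauge pressure.
#'
#' @param mz m/z in thomson.
#' @param duration Transient duration, s.
#' @param ion_radius Ion radius, m (user-supplied; e.g. from a structure).
#' @param model An [instrument_model()].
#' @param gas A [gas_model()].
#' @param ion_mass Optional ion mass in Da; if given, the centre-of-mass
#'   energy fraction and a relative energy-per-area figure are filled in.
#' @return A `collision_estimate` list: `path_length` (m), `ccs` (m^2),
#'   `number_density` (m^-3), `mean_free_path` (m), `expected_collisions`,
#'   `com_energy_fraction`, `energy_per_area` (relative units), and
#'   `vacuum_limit` flag set when the density is zero.
#' @examples
#' est <- expected_collisions(21343.1, 4.096, 17e-9,
#'                            gas = gas_model("xenon"))
#' est$expected_collisions   # order 10^1-10^2 for megadalton presets
#' @export
expected_collisions <- function(mz, duration, ion_radius,
                                model = instrument_model(),
                                gas = gas_model(),
                                ion_mass = NULL) {
  check_number(mz, "mz")
  check_number(duration, "duration")
  check_number(ion_radius, "ion_radius")
  len <- path_length(mz, duration, model)
  ccs <- ccs_from_radius(ion_radius, gas$gas_radius)
  n <- number_density(gas)
  vacuum <- (n * ccs) == 0
  mfp <- if (vacuum) Inf else 1 / (n * ccs)
  coll <- if (vacuum) 0 else len / mfp
  com <- if (is.null(ion_mass)) NA_real_ else
    com_energy_fraction(ion_mass, gas$gas_mass)
  epa <- if (is.null(ion_mass)) NA_real_ else com * len / ccs
  structure(
    list(path_length = len, ccs = ccs, number_density = n,
         mean_free_path = mfp, expected_collisions = coll,
         com_energy_fraction = com, energy_per_area = epa,
         vacuum_limit = vacuum),
    class = "collision_estimate")
}

#' @export
print.collision_estimate <- function(x, ...) {
  cat("<collision_estimate>\n")
  cat(sprintf("  path length    : %.4g m\n", x$path_length))
  cat(sprintf("  CCS            : %.4g m^2\n", x$ccs))
  cat(sprintf("  gas density    : %.4g m^-3\n", x$number_density))
  cat(sprintf("  mean free path : %.4g m\n", x$mean_free_path))
  cat(sprintf("  collisions     : %.3g%s\n", x$expected_collisions,
              if (x$vacuum_limit) " (vacuum limit)" else ""))
  invisible(x)
}

#' Centre-of-mass energy fraction of an ion-gas collision
#'
#' Fraction of the laboratory kinetic energy available in the centre-of-mass
#' frame, \eqn{m_{gas}/(m_{gas}+m_{ion})}. For megadalton ions colliding with
#' xenon this is of order 1e-5, one reason such particles shrug off hundreds
#' of collisions.
#'
#' @param ion_mass Ion mass, Da.
#' @param gas_mass Gas mass, Da.
#' @return Dimensionless fraction in (0, 1).
#' @export
com_energy_fraction <- function(ion_mass, gas_mass) {
  check_number(ion_mass, "ion_mass", scalar = FALSE)
  check_number(gas_mass, "gas_mass")
  gas_mass / (gas_mass + ion_mass)
}

#' Relative stability scaling with particle mass
#'
#' For a family of particles following a charge law \eqn{z \propto m^e}
#' (default e = 0.5, Rayleigh-like native-ESI charging), computes how
#' travelled distance, centre-of-mass collision energy, CCS and the energy
#' deposited per surface area scale with mass, normalized to 1 at a
#' reference mass (default 100 kDa). Distance scales as \eqn{(m/z)^{-1/2}},
#' COM energy as \eqn{z \, m_{gas}/(m_{gas}+m)} (lab energy proportional to
#' charge), CCS as \eqn{m^{2/3}} (constant density), and energy per area as
#' COM x distance / CCS. The steep drop of the last quantity with mass is
#' the plateau-of-stability argument for megadalton particles.
#'
#' @param masses Particle masses, Da.
#' @param reference_mass Normalization mass, Da (default 1e5).
#' @param charge_law_exponent Exponent e in \eqn{z \propto m^e}.
#' @param gas_mass Neutral gas mass, Da.
#' @return A data.frame with columns `mass`, `rel_distance`,
#'   `rel_com_energy`, `rel_ccs`, `rel_energy_per_area`.
#' @examples
#' stability_scaling_profile(c(1e5, 8e5))$rel_ccs  # 1, 4
#' @export
stability_scaling_profile <- function(masses, reference_mass = 1e5,
                                      charge_law_exponent = 0.5,
                                      gas_mass = 28.014) {
  check_number(masses, "masses", scalar = FALSE)
  check_number(reference_mass, "reference_mass")
  check_number(gas_mass, "gas_mass")
  raw <- function(m) {
    z <- m^charge_law_exponent
    mz <- m / z
    dist <- mz^(-0.5)
    com <- z * gas_mass / (gas_mass + m)
    ccs <- m^(2 / 3)
    list(dist = dist, com = com, ccs = ccs, epa = com * dist / ccs)
  }
  v <- raw(masses)
  r <- raw(reference_mass)
  data.frame(
    mass = masses,
    rel_distance = v$dist / r$dist,
    rel_com_energy = v$com / r$com,
    rel_ccs = v$ccs / r$ccs,
    rel_energy_per_area = v$epa / r$epa)
}
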