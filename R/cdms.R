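#' Convert normalized spectral intensity to charge
#'
#' Single-ion image-current peak height is linear in charge; under the
#' toolkit's normalization the conversion is a single gain factor (default
#' 175 charges per unit intensity).
#'
#' @param intensity Normalized peak intensity (>= 0); vectorized.
#' @param model An [instrument_model()].
#' @return Charge estimate (real-valued).
#' @export
intensity_to_charge <- function(intensity, model = instrument_model()) {
  check_number(intensity, "intensity", allow_zero = TRUE, scalar = FALSE)
  intensity * model$charge_gain
}

#' @noRd
new_cdms_ion <- function(mz, intensity, model, source,
                         subtract_proton = TRUE, trace_id = NA_integer_,
                         flags = "") {
  charge <- intensity_to_charge(intensity, model)
  mz_eff <- mz - (if (subtract_proton) model$proton_mass else 0)
  data.frame(trace_id = trace_id, mz = mz, intensity = intensity,
             charge = charge, charge_int = round(charge),
             mass = charge * mz_eff, source = source, flags = flags,
             stringsAsFactors = FALSE)
}

#' Drift-corrected CDMS ion from a chased trace
#'
#' For a trace that passed the stability filters, the per-segment drift is
#' small relative to the segment Fourier bin, so averaging the segment
#' intensities and m/z values recovers the undistorted peak height that a
#' drifting ion loses in the full-transient spectrum. Charge and mass are
#' derived from the averages.
#'
#' @param trace An `ion_trace` not marked rejected.
#' @param model An [instrument_model()].
#' @param subtract_proton Subtract charge x proton mass from the mass
#'   (default TRUE; negligible at MDa scale).
#' @return One-row CDMS ion data.frame: `trace_id`, `mz`, `intensity`,
#'   `charge`, `charge_int`, `mass`, `source = "drift_corrected"`, `flags`.
#' @export
drift_correct <- function(trace, model = instrument_model(),
                          subtract_proton = TRUE) {
  if (identical(trace$classification, "rejected"))
    abort_invalid("trace was rejected by filtering")
  ct <- trace$centroids
  new_cdms_ion(mean(ct$mz), mean(ct$intensity), model,
               source = "drift_corrected",
               subtract_proton = subtract_proton,
               trace_id = trace$trace_id,
               flags = paste(trace$flags, collapse = ";"))
}

#' CDMS ion straight from a full-transient centroid
#'
#' The direct (non-chased) path: one accepted full-transient centroid gives
#' one ion, `source = "eft_direct"`.
#'
#' @param centroid One-row centroid data.frame.
#' @param model An [instrument_model()].
#' @param subtract_proton As in [drift_correct()].
#' @return One-row CDMS ion data.frame.
#' @export
eft_ion <- function(centroid, model = instrument_model(),
                    subtract_proton = TRUE) {
  new_cdms_ion(centroid$mz, centroid$intensity, model,
               source = "eft_direct", subtract_proton = subtract_proton)
}

#' Filter split peaks in a full-transient spectrum
#'
#' A drifting ion smears its full-transient peak into a split shape:
#' satellite maxima near the main peak and/or an anomalously wide main
#' lobe. A centroid is rejected when a neighbouring local maximum within
#' `window_bins` Fourier bins exceeds the Dirichlet sidelobe level expected
#' for a clean peak by `satellite_fraction` of the main height, or when its
#' FWHM exceeds `fwhm_tol` times the theoretical width of an undrifted peak
#' (1.2067 / T Hz in magnitude mode). Drifts within the one-bin stability
#' margin pass untouched.
#'
#' @param spectrum The full-transient `ion_spectrum`.
#' @param centroids Centroid data.frame from [pick_peaks()].
#' @param model An [instrument_model()].
#' @param satellite_fraction Satellite threshold as a fraction of the main
#'   height (default 0.2), applied above the clean-peak sidelobe envelope.
#' @param window_bins Satellite search half-width in (padded) Fourier bins
#'   (default 10).
#' @param fwhm_tol FWHM tolerance factor (default 1.5).
#' @return The centroids with logical `accepted` and character `reason`
#'   columns.
#' @export
filter_split_peaks <- function(spectrum, centroids,
                               model = instrument_model(),
                               satellite_fraction = 0.2, window_bins = 10,
                               fwhm_tol = 1.5) {
  mag <- spectrum$magnitude
  n <- length(mag)
  theo_fwhm_hz <- 1.2067 / spectrum$effective_duration
  accepted <- rep(TRUE, nrow(centroids))
  reason <- rep("", nrow(centroids))
  for (i in seq_len(nrow(centroids))) {
    b <- which.min(abs(spectrum$frequency - centroids$frequency_hz[i]))
    h <- centroids$intensity[i]
    fw <- peak_fwhm(spectrum, min(max(b, 2L), n - 1L))
    if (!anyNA(fw) && (fw[2] - fw[1]) > fwhm_tol * theo_fwhm_hz) {
      accepted[i] <- FALSE; reason[i] <- "wide_peak"; next
    }
    lo <- max(2L, b - window_bins); hi <- min(n - 1L, b + window_bins)
    idx <- lo:hi
    idx <- idx[abs(idx - b) >= 2]
    locmax <- idx[mag[idx] > mag[idx - 1] & mag[idx] >= mag[idx + 1]]
    if (length(locmax) > 0) {
      dnat <- abs(locmax - b) * spectrum$df * spectrum$effective_duration
      excess <- mag[locmax] - h * sidelobe_envelope(dnat)
      if (any(excess > satellite_fraction * h)) {
        accepted[i] <- FALSE; reason[i] <- "satellite"
      }
    }
  }
  centroids$accepted <- accepted
  centroids$reason <- reason
  centroids
}

#' Mass histogram with per-mode Gaussian resolution
#'
#' Bins accepted ion masses and fits a Gaussian to each detected mode
#' (within +/- 3 sigma of the mode, iteratively) to report the mass
#' resolution mass / FWHM.
#'
#' @param ions CDMS ion data.frame (needs a `mass` column, >= 1 row).
#' @param bin_width Histogram bin width, Da.
#' @param min_mode_fraction Modes below this fraction of the tallest bin
#'   are ignored (default 0.2).
#' @return A `mass_histogram` list: `breaks`, `counts`, `mids` and a
#'   `modes` data.frame (`mass`, `sigma`, `resolution`, `n`).
#' @export
build_mass_histogram <- function(ions, bin_width,
                                 min_mode_fraction = 0.2) {
  check_number(bin_width, "bin_width")
  masses <- ions$mass
  if (length(masses) < 1) abort_invalid("need at least one ion")
  lo <- floor(min(masses) / bin_width) * bin_width
  breaks <- seq(lo, max(masses) + bin_width, by = bin_width)
  h <- graphics::hist(masses, breaks = breaks, plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  # candidate modes: local maxima above a fraction of the tallest bin
  cand <- which(counts >= pmax(c(-1, counts[-length(counts)]), 0) &
                  counts >= c(counts[-1], 0) &
                  counts >= min_mode_fraction * max(counts))
  # merge adjacent candidate bins
  modes <- list()
  if (length(cand) > 0) {
    grp <- cumsum(c(1, diff(cand) > 2))
    for (g in unique(grp)) {
      bins <- cand[grp == g]
      centre <- mids[bins[which.max(counts[bins])]]
      sel <- masses
      mu <- centre; sg <- max(bin_width, stats::sd(masses) / 4)
      for (it in 1:4) {
        w <- sel[abs(sel - mu) <= 3 * sg]
        if (length(w) < 3) break
        mu <- mean(w); sg <- max(stats::sd(w), bin_width / 4)
      }
      modes[[length(modes) + 1L]] <-
        data.frame(mass = mu, sigma = sg,
                   resolution = mu / (2 * sqrt(2 * log(2)) * sg),
                   n = sum(abs(masses - mu) <= 3 * sg))
    }
  }
  modes <- if (length(modes)) do.call(rbind, modes) else
    data.frame(mass = numeric(0), sigma = numeric(0),
               resolution = numeric(0), n = integer(0))
  # drop duplicate detections of the same mode
  if (nrow(modes) > 1) {
    keep <- !duplicated(round(modes$mass / (2 * bin_width)))
    modes <- modes[keep, , drop = FALSE]
  }
  structure(list(breaks = breaks, counts = counts, mids = mids,
                 modes = modes, n_ions = length(masses)),
            class = "mass_histogram")
}

#' @export
print.mass_histogram <- function(x, ...) {
  cat(sprintf("<mass_histogram> %d ions, %d bins\n", x$n_ions,
              length(x$counts)))
  if (nrow(x$modes) > 0)
    for (i in seq_len(nrow(x$modes)))
      cat(sprintf("  mode %.4g Da, sigma %.3g Da, R = %.0f (n = %d)\n",
                  x$modes$mass[i], x$modes$sigma[i], x$modes$resolution[i],
                  x$modes$n[i]))
  invisible(x)
}

#' Survival ratio from a two-half segmented transform
#'
#' Splits the transient in two halves, processes each under the
#' duration-invariant normalization, and returns second-half over
#' first-half peak intensity near the given m/z — a semiquantitative proxy
#' for ion persistence (1 for a stable ion, ~0.5 for an ion lost at 75% of
#' the transient, 0 for one lost at half-time).
#'
#' @param transient A `transient`.
#' @param mz Ion m/z, Th.
#' @param model An [instrument_model()].
#' @param snr_threshold Detection requirement in the first half (in
#'   noise-SD units; the default 8 stays above the maximum expected from
#'   noise alone over a several-hundred-bin search window).
#' @param mz_tol_fraction Search window around `mz` (default 0.5%).
#' @return Ratio (second half / first half peak intensity).
#' @export
survival_ratio <- function(transient, mz, model = instrument_model(),
                           snr_threshold = 8, mz_tol_fraction = 0.005) {
  check_number(mz, "mz")
  n <- transient$n_samples
  half <- floor(n / 2)
  win <- c(mz * (1 - mz_tol_fraction), mz * (1 + mz_tol_fraction))
  peak_height <- function(samples) {
    sp <- compute_spectrum(new_transient(samples, transient$sample_rate),
                           model)
    bins <- bins_for_mz_range(sp, win, model)
    if (length(bins) < 3) abort_invalid("mz window too narrow")
    list(height = max(sp$magnitude[bins]),
         noise = spectrum_noise_sd(sp))
  }
  p1 <- peak_height(transient$samples[seq_len(half)])
  if (p1$height < snr_threshold * p1$noise)
    abort_invalid("ion not detectable in the first half")
  p2 <- peak_height(transient$samples[(half + 1):n])
  p2$height / p1$height
}

#' Charge precision versus transient time
#'
#' Standard deviation of per-ion charge estimates at each duration, fitted
#' with a power law sigma_z(t) = A t^B. White detector noise predicts
#' B = -0.5 (the square-root gain of longer transients). A noiseless
#' ensemble is flagged degenerate instead of fitted.
#'
#' @param charges_by_duration Named or unnamed list of numeric charge
#'   vectors, one per duration.
#' @param durations Durations, s (>= 3).
#' @return List: `durations`, `sigma`, `fit` (a `scaling_fit` or NULL),
#'   `degenerate`.
#' @export
charge_sigma_vs_time <- function(charges_by_duration, durations) {
  if (length(charges_by_duration) != length(durations) ||
      length(durations) < 3)
    abort_invalid("need >= 3 durations matching the charge lists")
  sigma <- vapply(charges_by_duration, stats::sd, 0)
  if (all(sigma < 1e-9))
    return(list(durations = durations, sigma = sigma, fit = NULL,
                degenerate = TRUE))
  list(durations = durations, sigma = sigma,
       fit = fit_power_law(durations, sigma), degenerate = FALSE)
}

#' Signal-utilization bookkeeping for drift correction
#'
#' How much of the recorded single-ion signal survives analysis: the direct
#' path accepts `eft_accepted` ions and rejects `eft_rejected` split peaks;
#' frequency chasing recovers `chase_recovered` of the rejected ones.
#' Reports utilization fractions and the fold improvement.
#'
#' @param eft_accepted,eft_rejected,chase_recovered Non-negative counts;
#'   `chase_recovered <= eft_rejected`.
#' @return A `sampling_report` list: `detected`, `accepted_direct`,
#'   `rejected_split`, `recovered`, `utilization_direct`,
#'   `utilization_corrected`, `fold_improvement`.
#' @examples
#' # 1.5% direct utilization recovered to 34.5% is a 23-fold gain
#' sampling_report(15, 985, 330)$fold_improvement
#' @export
sampling_report <- function(eft_accepted, eft_rejected, chase_recovered) {
  check_number(eft_accepted, "eft_accepted", allow_zero = TRUE)
  check_number(eft_rejected, "eft_rejected", allow_zero = TRUE)
  check_number(chase_recovered, "chase_recovered", allow_zero = TRUE)
  if (chase_recovered > eft_rejected)
    abort_invalid("chase_recovered cannot exceed eft_rejected")
  detected <- eft_accepted + eft_rejected
  if (detected == 0) abort_invalid("no ions detected")
  u0 <- eft_accepted / detected
  u1 <- (eft_accepted + chase_recovered) / detected
  structure(list(detected = detected, accepted_direct = eft_accepted,
                 rejected_split = eft_rejected,
                 recovered = chase_recovered,
                 utilization_direct = u0, utilization_corrected = u1,
                 fold_improvement = if (u0 > 0) u1 / u0 else Inf),
            class = "sampling_report")
}

#' @export
print.sampling_report <- function(x, ...) {
  cat(sprintf(
    "<sampling_report> %d detected: %.1f%% direct -> %.1f%% corrected (%.3gx)\n",
    x$detected, 100 * x$utilization_direct,
    100 * x$utilization_corrected, x$fold_improvement))
  invisible(x)
}
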