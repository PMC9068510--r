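#' Plan overlapping analysis segments for frequency chasing
#'
#' Divides a transient of the given duration into `n_segments` equal-length
#' windows with fractional overlap; with 50% overlap and n segments the
#' window length is duration / ((n + 1) / 2) (e.g. 15 segments over 1 s give
#' 0.125 s windows). Windows exactly cover `[0, duration]`.
#'
#' @param duration Transient duration, s.
#' @param n_segments Number of windows (default 15 per second, minimum 2).
#' @param overlap_fraction Fractional overlap in `[0, 1)` (default 0.5).
#' @return A `segmentation_plan` data.frame with columns `segment_index`,
#'   `start`, `length` (s).
#' @export
plan_segments <- function(duration, n_segments = max(2L, round(15 * duration)),
                          overlap_fraction = 0.5) {
  check_number(duration, "duration")
  check_number(n_segments, "n_segments")
  check_number(overlap_fraction, "overlap_fraction", allow_zero = TRUE)
  if (n_segments < 2 || n_segments != round(n_segments))
    abort_invalid("n_segments must be an integer >= 2")
  if (overlap_fraction >= 1)
    abort_invalid("overlap_fraction must be in [0, 1)")
  len <- duration / ((n_segments - 1) * (1 - overlap_fraction) + 1)
  starts <- (seq_len(n_segments) - 1) * len * (1 - overlap_fraction)
  plan <- data.frame(segment_index = seq_len(n_segments),
                     start = starts, length = len)
  structure(plan, class = c("segmentation_plan", "data.frame"),
            duration = duration, overlap_fraction = overlap_fraction)
}

#' Per-segment centroids of a transient
#'
#' Computes a magnitude-mode spectrum for each window of the plan (under the
#' same duration-invariant normalization as the full transient, so segment
#' intensities of a stable ion match the full-transient intensity) and picks
#' peaks in each. A failing segment is skipped with a warning; the others
#' are still processed.
#'
#' @param transient A `transient`.
#' @param plan A [plan_segments()] result (default: 15 segments/s, 50%
#'   overlap).
#' @param model An [instrument_model()].
#' @param snr_threshold Peak threshold passed to [pick_peaks()].
#' @param mz_range Optional m/z restriction.
#' @return Centroid data.frame with `segment_index` filled; the plan is kept
#'   in attribute `"plan"`.
#' @export
segmented_centroids <- function(transient, plan = NULL,
                                model = instrument_model(),
                                snr_threshold = 10, mz_range = NULL) {
  plan <- plan %||% plan_segments(transient$duration)
  fs <- transient$sample_rate
  out <- vector("list", nrow(plan))
  for (s in seq_len(nrow(plan))) {
    out[[s]] <- tryCatch({
      i0 <- floor(plan$start[s] * fs) + 1
      nw <- round(plan$length[s] * fs)
      i1 <- min(i0 + nw - 1, transient$n_samples)
      seg <- new_transient(transient$samples[i0:i1], fs)
      sp <- compute_spectrum(seg, model)
      ct <- pick_peaks(sp, snr_threshold = snr_threshold,
                       mz_range = mz_range, model = model)
      if (nrow(ct) > 0) ct$segment_index <- plan$segment_index[s]
      ct
    }, error = function(e) {
      warning("segment ", s, " failed: ", conditionMessage(e), call. = FALSE)
      NULL
    })
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(mz = numeric(0), frequency_hz = numeric(0),
                      intensity = numeric(0), fwhm_th = numeric(0),
                      snr = numeric(0), segment_index = integer(0))
  attr(res, "plan") <- plan
  res
}

#' Drop centroids with close neighbours in the same segment
#'
#' Segment spectra have much lower resolving power than the full transient,
#' so only ions without a neighbour within `min_separation_bins` times the
#' local segment FWHM are traced; both members of a close pair are dropped
#' (this also prevents misassignment between two crossing ion species).
#'
#' @param centroids Segmented centroid data.frame (needs `fwhm_th`).
#' @param min_separation_bins Separation threshold in units of the segment
#'   FWHM (default 2).
#' @return The filtered data.frame.
#' @export
isolate_candidates <- function(centroids, min_separation_bins = 2) {
  check_number(min_separation_bins, "min_separation_bins")
  keep <- rep(TRUE, nrow(centroids))
  for (s in unique(centroids$segment_index)) {
    idx <- which(centroids$segment_index == s)
    if (length(idx) < 2) next
    mz <- centroids$mz[idx]
    fw <- centroids$fwhm_th[idx]
    fw[is.na(fw)] <- stats::median(fw, na.rm = TRUE)
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (a == b) next
        if (abs(mz[a] - mz[b]) <
            min_separation_bins * max(fw[a], fw[b], na.rm = TRUE)) {
          keep[idx[a]] <- FALSE
          keep[idx[b]] <- FALSE
        }
      }
    }
  }
  out <- centroids[keep, , drop = FALSE]
  attr(out, "plan") <- attr(centroids, "plan")
  out
}

#' @noRd
new_ion_trace <- function(centroids, trace_id = NA_integer_) {
  centroids <- centroids[order(centroids$segment_index), , drop = FALSE]
  structure(
    list(centroids = centroids,
         trace_id = trace_id,
         mz_std = stats::sd(centroids$mz),
         intensity_std = stats::sd(centroids$intensity),
         classification = NA_character_,
         assigned_charge = NA_real_,
         flags = character(0),
         detail = list()),
    class = "ion_trace")
}

#' @export
print.ion_trace <- function(x, ...) {
  cat(sprintf(
    "<ion_trace %s> %d segments, m/z %.2f, sd(m/z) %.3g, sd(int) %.3g, %s\n",
    ifelse(is.na(x$trace_id), "-", x$trace_id), nrow(x$centroids),
    mean(x$centroids$mz), x$mz_std, x$intensity_std,
    ifelse(is.na(x$classification), "unclassified", x$classification)))
  invisible(x)
}

#' Chain per-segment centroids into ion traces
#'
#' Greedy nearest-in-m/z matching from the earliest appearance: in each
#' segment, active traces (in order of decreasing mean intensity) claim
#' their closest unused centroid within `max_match_fraction` of their last
#' m/z; distance ties go to the more intense candidate. Each centroid is
#' used at most once; traces may bridge up to `max_gap` missing segments and
#' traces shorter than `min_length_fraction` of the segment count are
#' discarded. Unclaimed centroids seed new traces.
#'
#' @param centroids Segmented centroid data.frame (e.g. from
#'   [isolate_candidates()]).
#' @param n_segments Total number of segments (default: from the plan
#'   attribute or the maximum segment index seen).
#' @param max_match_fraction Maximum m/z step between consecutive segments,
#'   as a fraction of the current m/z (default 0.01; large enough for a
#'   single-charge-loss jump at megadalton charge states).
#' @param max_gap Maximum number of consecutive missing segments bridged.
#' @param min_length_fraction Minimum trace length as a fraction of
#'   `n_segments`.
#' @param pair_doublets Attempt to rejoin charge-loss doublets (default
#'   TRUE). The analysis window that contains the frequency step of a
#'   charge-stripping event yields interference artefacts that can break
#'   the chain there; a fragment that ends just before another fragment
#'   starts at higher m/z, with the jump matching the z/(z-1) spacing of
#'   an integer charge, is merged back into one trace (flagged
#'   `doublet_paired`) before the length filter.
#' @param doublet_gap Maximum segment gap bridged when pairing doublets.
#' @return List of `ion_trace` objects.
#' @export
trace_ions <- function(centroids, n_segments = NULL,
                       max_match_fraction = 0.01, max_gap = 1,
                       min_length_fraction = 0.6, pair_doublets = TRUE,
                       doublet_gap = 4) {
  plan <- attr(centroids, "plan")
  n_segments <- n_segments %||% (if (!is.null(plan)) nrow(plan) else
    max(centroids$segment_index, 0))
  if (n_segments < 2) abort_invalid("need at least 2 segments")
  active <- list()   # each: rows, last_mz, mean_int, gap
  closed <- list()
  for (s in seq_len(n_segments)) {
    rows <- which(centroids$segment_index == s)
    used <- rep(FALSE, length(rows))
    if (length(active) > 0) {
      ord <- order(vapply(active, function(tr) tr$mean_int, 0),
                   decreasing = TRUE)
      for (ti in ord) {
        tr <- active[[ti]]
        avail <- which(!used)
        if (length(avail) == 0) { active[[ti]]$gap <- tr$gap + 1L; next }
        d <- abs(centroids$mz[rows[avail]] - tr$last_mz)
        ok <- d <= max_match_fraction * tr$last_mz
        if (!any(ok)) { active[[ti]]$gap <- tr$gap + 1L; next }
        cand <- avail[ok]; dc <- d[ok]
        near <- cand[dc <= min(dc) * (1 + 1e-9)]
        pick <- near[which.max(centroids$intensity[rows[near]])]
        used[pick] <- TRUE
        r <- rows[pick]
        active[[ti]]$rows <- c(tr$rows, r)
        active[[ti]]$last_mz <- centroids$mz[r]
        active[[ti]]$mean_int <-
          mean(centroids$intensity[active[[ti]]$rows])
        active[[ti]]$gap <- 0L
      }
    }
    # retire traces that exceeded the gap allowance
    if (length(active) > 0) {
      over <- vapply(active, function(tr) tr$gap > max_gap, TRUE)
      closed <- c(closed, active[over])
      active <- active[!over]
    }
    # unclaimed centroids start new traces
    for (r in rows[!used])
      active <- c(active, list(list(rows = r, last_mz = centroids$mz[r],
                                    mean_int = centroids$intensity[r],
                                    gap = 0L)))
  }
  closed <- c(closed, active)
  flags <- vector("list", length(closed))
  if (pair_doublets && length(closed) >= 2) {
    paired <- pair_doublet_fragments(closed, centroids, doublet_gap)
    closed <- paired$fragments
    flags <- paired$flags
  }
  min_len <- max(2, ceiling(min_length_fraction * n_segments))
  traces <- list()
  for (i in seq_along(closed)) {
    if (length(closed[[i]]$rows) < min_len) next
    tr <- new_ion_trace(centroids[closed[[i]]$rows, , drop = FALSE],
                        trace_id = length(traces) + 1L)
    tr$flags <- flags[[i]] %||% character(0)
    traces[[length(traces) + 1L]] <- tr
  }
  traces
}

# Rejoin trace fragments split at a charge-stripping event: fragment A
# ending shortly before fragment B starts at higher m/z, with the m/z jump
# matching z/(z-1) for an integer charge and both sides internally stable.
#' @noRd
pair_doublet_fragments <- function(fragments, centroids, doublet_gap) {
  n <- length(fragments)
  flags <- vector("list", n)
  segs_of <- lapply(fragments, function(fr)
    centroids$segment_index[fr$rows])
  mz_of <- lapply(fragments, function(fr) centroids$mz[fr$rows])
  used <- rep(FALSE, n)
  out <- list(); out_flags <- list()
  # a fragment is "coherent" if most of its centroids sit near its median
  # m/z; the odd interference-biased point from the step window is allowed
  coherent <- function(mz) length(mz) >= 3 &&
    mean(abs(mz - stats::median(mz)) < 2) >= 0.7
  ord <- order(vapply(segs_of, min, 0))
  for (ia in ord) {
    if (used[ia]) next
    a_mz <- mz_of[[ia]]; a_seg <- segs_of[[ia]]
    merged <- FALSE
    if (coherent(a_mz)) {
      for (ib in ord) {
        if (ib == ia || used[ib]) next
        b_mz <- mz_of[[ib]]; b_seg <- segs_of[[ib]]
        if (!coherent(b_mz)) next
        gap <- min(b_seg) - max(a_seg)
        if (gap < 0 || gap > doublet_gap) next
        mza <- stats::median(a_mz); mzb <- stats::median(b_mz)
        if (mzb <= mza) next
        z <- mzb / (mzb - mza)
        if (z <= 1 || abs(z - round(z)) > 0.35) next
        fragments[[ia]]$rows <- c(fragments[[ia]]$rows,
                                  fragments[[ib]]$rows)
        used[ib] <- TRUE
        flags[[ia]] <- union(flags[[ia]], "doublet_paired")
        merged <- TRUE
        break
      }
    }
    out[[length(out) + 1L]] <- fragments[[ia]]
    out_flags[[length(out)]] <- flags[[ia]] %||% character(0)
    used[ia] <- TRUE
  }
  list(fragments = out, flags = out_flags)
}

#' Filter traces on m/z and intensity stability
#'
#' Marks traces whose per-segment standard deviation exceeds 4 Th in m/z or
#' 0.2 in normalized intensity as `rejected`; the survivors proceed to
#' drift correction. Traces already classified as `charge_loss` are exempt:
#' the quantized m/z jump inflates their m/z SD by construction, and they
#' feed the direct charge/mass doublet path rather than segment averaging.
#'
#' @param traces List of `ion_trace` objects.
#' @param mz_std_max m/z SD threshold, Th (default 4).
#' @param intensity_std_max Normalized-intensity SD threshold (default 0.2).
#' @return The list with rejected traces marked.
#' @export
filter_traces <- function(traces, mz_std_max = 4, intensity_std_max = 0.2) {
  lapply(traces, function(tr) {
    if (identical(tr$classification, "charge_loss")) return(tr)
    if (isTRUE(tr$mz_std > mz_std_max) ||
        isTRUE(tr$intensity_std > intensity_std_max)) {
      tr$classification <- "rejected"
      tr$flags <- union(tr$flags, "std_filter")
    }
    tr
  })
}

#' Classify the drift behaviour of a trace
#'
#' Reproduces the three observed single-ion behaviour classes: `stable`
#' (total m/z excursion below one full-transient Fourier bin, converted to
#' m/z units at the trace position), `charge_loss` (a single upward
#' between-segment jump whose magnitude matches the z/(z-1) spacing for an
#' integer charge within tolerance) and `gradual_loss` (everything else:
#' progressive desolvation). Jumps that are large but match no integer
#' charge within tolerance are flagged `ambiguous_jump` and the trace is
#' rejected rather than guessed.
#'
#' @param trace An `ion_trace` that passed [filter_traces()].
#' @param full_duration Full transient duration, s (sets the Fourier bin).
#' @param model An [instrument_model()].
#' @param jump_min_bins Minimum jump size, in Fourier bins, considered a
#'   candidate charge loss (default 3).
#' @param integer_tol Baseline tolerance on |z - round(z)| (default 0.3);
#'   widened to 3x the propagated centroid uncertainty when larger.
#' @return The trace with `classification` (and for charge losses
#'   `assigned_charge` and `detail`: event segment, z estimate and
#'   uncertainty, m/z before/after) filled in.
#' @export
classify_trace <- function(trace, full_duration, model = instrument_model(),
                           jump_min_bins = 3, integer_tol = 0.3) {
  if (identical(trace$classification, "rejected"))
    abort_invalid("trace was rejected by filtering")
  ct <- trace$centroids
  if (nrow(ct) < 2) abort_invalid("trace needs >= 2 segments")
  mz <- ct$mz
  mzm <- mean(mz)
  dfbin <- 1 / (full_duration * model$zero_pad_factor)
  f <- mz_to_freq(mzm, model)
  bin_mz <- 2 * mzm * dfbin / f   # |d(mz)/df| = 2 mz / f
  if (max(mz) - min(mz) < bin_mz) {
    trace$classification <- "stable"
    return(trace)
  }
  d <- diff(mz)
  k <- which.max(d)
  if (d[k] > jump_min_bins * bin_mz) {
    before <- mz[seq_len(k)]
    after <- mz[(k + 1):length(mz)]
    # robust centroid scatter and side positions: the window containing
    # the frequency step can leave interference-biased centroids next to
    # the jump, so medians are used over the adjacent segments
    steps <- d[-k]
    sig_c <- if (length(steps) >= 2) stats::mad(steps) / sqrt(2) else 0
    nb <- min(length(before), 5)
    na <- min(length(after), 5)
    mzb <- stats::median(utils::tail(before, nb))
    mza <- stats::median(utils::head(after, na))
    sb <- 1.25 * sig_c / sqrt(nb)
    sa <- 1.25 * sig_c / sqrt(na)
    est <- charge_from_pair(mzb, mza, sb, sa)
    tol <- max(integer_tol, 3 * est$z_uncertainty)
    if (est$z_estimate > 1 &&
        abs(est$z_estimate - round(est$z_estimate)) < tol) {
      trace$classification <- "charge_loss"
      trace$assigned_charge <- round(est$z_estimate)
      trace$detail <- list(event_segment = ct$segment_index[k + 1],
                           z_estimate = est$z_estimate,
                           z_uncertainty = est$z_uncertainty,
                           mz_before = mzb, mz_after = mza,
                           mz_before_sigma = sb, mz_after_sigma = sa)
      return(trace)
    }
    trace$classification <- "rejected"
    trace$flags <- union(trace$flags, "ambiguous_jump")
    return(trace)
  }
  trace$classification <- "gradual_loss"
  trace
}

#' Assign a charge to a trace from its intensity
#'
#' Mean segment intensity times the instrument charge gain, rounded to the
#' nearest integer.
#'
#' @param trace An `ion_trace`.
#' @param model An [instrument_model()].
#' @return The trace with `assigned_charge` set.
#' @export
assign_charge <- function(trace, model = instrument_model()) {
  trace$assigned_charge <-
    round(intensity_to_charge(mean(trace$centroids$intensity), model))
  trace
}

#' Convert a trace's frequency drift to neutral loss
#'
#' With the charge known, an m/z step between consecutive chased segments
#' converts to daltons of neutral loss: loss_k = -z (mz_k - mz_(k-1)); the
#' cumulative column is the running sum (zero at the first segment).
#'
#' @param trace An `ion_trace`.
#' @param charge Charge used for the conversion (default: the trace's
#'   `assigned_charge`).
#' @return A `neutral_loss_profile` data.frame: `segment_index`, `loss_da`,
#'   `cumulative_da`; the charge used is kept as an attribute.
#' @export
drift_to_loss <- function(trace, charge = NULL) {
  z <- charge %||% trace$assigned_charge
  if (is.null(z) || is.na(z)) abort_invalid("charge is required")
  ct <- trace$centroids
  loss <- c(0, -z * diff(ct$mz))
  out <- data.frame(segment_index = ct$segment_index, loss_da = loss,
                    cumulative_da = cumsum(loss))
  structure(out, class = c("neutral_loss_profile", "data.frame"), charge = z)
}

#' Fit the linear-plus-exponential neutral-loss model
#'
#' Nonlinear least squares of per-segment losses
#' \eqn{loss_k = \alpha + \beta e^{-(k-1)/\tau}} (k = 1-based segment index),
#' the signature of a constant collision-driven loss rate during detection
#' plus an exponentially relaxing activation acquired at injection. Both
#' amplitudes are constrained non-negative. When the data carry no
#' detectable exponential component the fit degenerates to the constant
#' term and tau is flagged unidentifiable.
#'
#' @param losses Mean per-segment losses, Da (>= 4 segments).
#' @param k Segment indices (default `seq_along(losses)`).
#' @return A `decay_fit` list: `alpha` (Da/segment), `beta` (Da), `tau`
#'   (segments), `r2`, `converged`, `flags`, `fitted`.
#' @export
fit_decay_model <- function(losses, k = seq_along(losses)) {
  if (length(losses) < 4) abort_invalid("need >= 4 segments")
  sst <- sum((losses - mean(losses))^2)
  r2_of <- function(fitted) if (sst == 0) 1 else
    1 - sum((losses - fitted)^2) / sst
  constant_fit <- function(flags) {
    a <- max(mean(losses), 0)
    structure(list(alpha = a, beta = 0, tau = NA_real_,
                   r2 = r2_of(rep(a, length(losses))), converged = TRUE,
                   flags = flags, fitted = rep(a, length(losses))),
              class = "decay_fit")
  }
  alpha0 <- max(mean(utils::tail(losses, 3)), 0)
  beta0 <- max(losses[1] - alpha0, 1e-8)
  excess <- losses - alpha0
  pos <- which(excess > 0 & k <= stats::median(k))
  tau0 <- if (length(pos) >= 3) {
    sl <- stats::coef(stats::lm(log(excess[pos]) ~ k[pos]))[2]
    if (is.finite(sl) && sl < 0) min(max(-1 / sl, 0.2), length(losses)) else 2
  } else 2
  fit <- tryCatch(
    minpack.lm::nlsLM(
      losses ~ alpha + beta * exp(-(k - 1) / tau),
      start = list(alpha = alpha0, beta = beta0, tau = tau0),
      lower = c(alpha = 0, beta = 0, tau = 0.05),
      upper = c(alpha = Inf, beta = Inf, tau = 10 * length(losses)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(constant_fit(if (sst <= 1e-12 * max(abs(losses))^2)
      "tau_unidentifiable" else "non_convergence"))
  cf <- stats::coef(fit)
  # the exponential term is identifiable only if its decay across the
  # observed segments rises above the residual scatter
  resid_sd <- stats::sd(losses - stats::fitted(fit))
  drop <- cf[["beta"]] *
    (1 - exp(-(length(losses) - 1) / cf[["tau"]]))
  if (cf[["beta"]] < 0.05 * max(cf[["alpha"]], 1e-12) ||
      drop < 2 * resid_sd)
    return(constant_fit("tau_unidentifiable"))
  fitted <- stats::fitted(fit)
  structure(list(alpha = unname(cf[["alpha"]]), beta = unname(cf[["beta"]]),
                 tau = unname(cf[["tau"]]), r2 = r2_of(fitted),
                 converged = TRUE, flags = character(0),
                 fitted = as.numeric(fitted)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> loss_k = %.4g + %.4g exp(-(k-1)/%.4g) Da (r2 = %.5f)%s\n",
    x$alpha, x$beta, x$tau, x$r2,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
    else ""))
  invisible(x)
}

#' Charge from a charge-loss doublet
#'
#' A single charge loss moves an ion from m/z x1 = M/z to x2 = M/(z-1), so
#' z = x2 / (x2 - x1) independent of any calibration. The uncertainty is
#' propagated from the centroid uncertainties of the two positions.
#'
#' @param mz_before,mz_after m/z before and after the loss (after > before).
#' @param sigma_before,sigma_after Centroid uncertainties, Th.
#' @return List: `z_estimate`, `z_uncertainty`.
#' @examples
#' charge_from_pair(99, 100)  # z = 100
#' @export
charge_from_pair <- function(mz_before, mz_after,
                             sigma_before = 0, sigma_after = 0) {
  check_number(mz_before, "mz_before")
  check_number(mz_after, "mz_after")
  if (mz_after <= mz_before)
    abort_invalid("mz_after must exceed mz_before")
  d <- mz_after - mz_before
  z <- mz_after / d
  sz <- sqrt((mz_after * sigma_before)^2 + (mz_before * sigma_after)^2) / d^2
  list(z_estimate = z, z_uncertainty = sz)
}

#' Build a charge-loss event record
#'
#' @param mz_before,mz_after m/z before/after the loss, Th.
#' @param mz_before_sigma,mz_after_sigma Centroid uncertainties, Th.
#' @param event_segment Segment index at which the jump occurred.
#' @return A `charge_loss_event` list including the charge estimate.
#' @export
charge_loss_event <- function(mz_before, mz_after, mz_before_sigma = 0,
                              mz_after_sigma = 0, event_segment = NA) {
  est <- charge_from_pair(mz_before, mz_after, mz_before_sigma,
                          mz_after_sigma)
  structure(list(mz_before = mz_before, mz_after = mz_after,
                 mz_before_sigma = mz_before_sigma,
                 mz_after_sigma = mz_after_sigma,
                 z_estimate = est$z_estimate,
                 z_uncertainty = est$z_uncertainty,
                 event_segment = event_segment),
            class = "charge_loss_event")
}

#' Direct single-ion mass from a charge-loss event
#'
#' mass = round(z) x (mz_before - proton_mass) by default; set
#' `subtract_proton = FALSE` to use the ionic m/z as is (the two differ by
#' only ~150 Da at megadalton scale). The uncertainty combines the m/z
#' centroid uncertainty and the propagated z uncertainty. A z estimate
#' further than `integer_tol` from an integer is recorded (and signalled)
#' as a warning rather than an error.
#'
#' @param event A [charge_loss_event()].
#' @param model An [instrument_model()].
#' @param subtract_proton Subtract one proton mass per charge from m/z.
#' @param integer_tol Allowed |z - round(z)| before warning (default 0.3).
#' @return List: `mass` (Da), `uncertainty` (Da), `z_rounded`,
#'   `integer_deviation`, `warned`.
#' @export
mass_from_pair <- function(event, model = instrument_model(),
                           subtract_proton = TRUE, integer_tol = 0.3) {
  z <- event$z_estimate
  zr <- round(z)
  dev <- abs(z - zr)
  warned <- dev > integer_tol
  if (warned)
    warning(sprintf("z estimate %.3f deviates %.3f from integer", z, dev),
            call. = FALSE)
  mz_eff <- event$mz_before -
    (if (subtract_proton) model$proton_mass else 0)
  mass <- zr * mz_eff
  unc <- sqrt((zr * event$mz_before_sigma)^2 +
                (mz_eff * event$z_uncertainty)^2)
  list(mass = mass, uncertainty = unc, z_rounded = zr,
       integer_deviation = dev, warned = warned)
}

#' Detect mirrored radial-modulation sidebands
#'
#' Radial ion motion amplitude-modulates the axial image current, producing
#' a pair of sidebands above and below the axial frequency that are mirror
#' images of each other. This locates the strongest symmetric pair within
#' `search_width` Hz of the main peak and scores the mirror symmetry as the
#' correlation between the lower-sideband profile and the
#' frequency-reversed upper-sideband profile.
#'
#' @param spectrum An `ion_spectrum`.
#' @param main_centroid One-row centroid of the main (axial) peak.
#' @param search_width Search half-width, Hz.
#' @param model An [instrument_model()].
#' @param snr_threshold Sideband detection threshold in noise-SD units.
#' @return A `sideband_report` list: `found`, `main_mz`,
#'   `upper_offset_hz`, `lower_offset_hz`, `mirror_symmetry_score`. With no
#'   sidebands above noise, `found` is FALSE (not an error).
#' @export
detect_radial_sidebands <- function(spectrum, main_centroid, search_width,
                                    model = instrument_model(),
                                    snr_threshold = 5) {
  check_number(search_width, "search_width")
  f0 <- main_centroid$frequency_hz
  noise_sd <- spectrum_noise_sd(spectrum)
  thr <- snr_threshold * noise_sd
  mag <- spectrum$magnitude
  freq <- spectrum$frequency
  nat <- 1 / spectrum$effective_duration        # natural bin, Hz
  empty <- structure(list(found = FALSE, main_mz = main_centroid$mz,
                          upper_offset_hz = NA_real_,
                          lower_offset_hz = NA_real_,
                          mirror_symmetry_score = NA_real_),
                     class = "sideband_report")
  main_h <- main_centroid$intensity
  apex_in <- function(flo, fhi) {
    idx <- which(freq >= flo & freq <= fhi)
    idx <- idx[idx > 1 & idx < length(mag)]
    idx <- idx[mag[idx] > mag[idx - 1] & mag[idx] >= mag[idx + 1] &
                 mag[idx] > thr]
    # a genuine sideband must rise above the main peak's own sidelobes
    if (length(idx) > 0) {
      dnat <- abs(freq[idx] - f0) / nat
      idx <- idx[mag[idx] > 1.2 * main_h * sidelobe_envelope(dnat) +
                   3 * noise_sd]
    }
    if (length(idx) == 0) return(NA_integer_)
    idx[which.max(mag[idx])]
  }
  bu <- apex_in(f0 + 2 * nat, f0 + search_width)
  if (is.na(bu)) return(empty)
  up <- centroid_parabola(spectrum, bu, model)
  off <- up$frequency_hz - f0
  bl <- apex_in(f0 - off - 2 * nat, f0 - off + 2 * nat)
  if (is.na(bl)) return(empty)
  lo <- centroid_parabola(spectrum, bl, model)
  nw <- 2L * spectrum$zero_pad_factor   # +/- 2 natural bins of profile
  if (bu - nw < 1 || bu + nw > length(mag) || bl - nw < 1) return(empty)
  score <- stats::cor(mag[(bl - nw):(bl + nw)],
                      rev(mag[(bu - nw):(bu + nw)]))
  structure(list(found = TRUE, main_mz = main_centroid$mz,
                 upper_offset_hz = off,
                 lower_offset_hz = f0 - lo$frequency_hz,
                 mirror_symmetry_score = score),
            class = "sideband_report")
}

#' @export
print.sideband_report <- function(x, ...) {
  if (!x$found) cat("<sideband_report> no sidebands above noise\n")
  else cat(sprintf(
    "<sideband_report> offsets +%.2f / -%.2f Hz, mirror score %.3f\n",
    x$upper_offset_hz, x$lower_offset_hz, x$mirror_symmetry_score))
  invisible(x)
}
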