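#' Run the full frequency-chasing pipeline on one transient
#'
#' Convenience wrapper chaining [plan_segments()], [segmented_centroids()],
#' [isolate_candidates()], [trace_ions()], [filter_traces()],
#' [classify_trace()] and charge assignment, then converting every retained
#' trace to a per-segment neutral-loss profile and (when enough gradual-loss
#' data exist) fitting the linear-plus-exponential decay model to the mean
#' per-segment losses.
#'
#' @param transient A `transient`.
#' @param model An [instrument_model()].
#' @param n_segments,overlap_fraction Segmentation (defaults 15/s, 0.5).
#' @param snr_threshold Segment peak-picking threshold.
#' @param mz_range Optional m/z restriction.
#' @param min_separation_bins Isolation threshold ([isolate_candidates()]).
#' @return List: `centroids`, `traces` (classified), `losses` (list of
#'   `neutral_loss_profile`), `decay_fit` (or NULL), `plan`.
#' @export
chase_transient <- function(transient, model = instrument_model(),
                            n_segments = max(2L,
                                             round(15 * transient$duration)),
                            overlap_fraction = 0.5, snr_threshold = 10,
                            mz_range = NULL, min_separation_bins = 2) {
  plan <- plan_segments(transient$duration, n_segments, overlap_fraction)
  cents <- segmented_centroids(transient, plan, model,
                               snr_threshold = snr_threshold,
                               mz_range = mz_range)
  cents <- isolate_candidates(cents, min_separation_bins)
  traces <- trace_ions(cents, n_segments = n_segments)
  # classify first: charge-loss doublets would fail the m/z-stability
  # filter on the size of their quantized jump alone
  traces <- lapply(traces, function(tr)
    classify_trace(tr, transient$duration, model))
  traces <- filter_traces(traces)
  traces <- lapply(traces, function(tr) {
    if (is.na(tr$assigned_charge) &&
        !identical(tr$classification, "rejected"))
      tr <- assign_charge(tr, model)
    tr
  })
  retained <- Filter(function(tr)
    tr$classification %in% c("stable", "gradual_loss"), traces)
  losses <- lapply(retained, drift_to_loss)
  decay <- NULL
  grad <- Filter(function(tr)
    identical(tr$classification, "gradual_loss"), retained)
  if (length(grad) >= 1) {
    prof <- lapply(grad, drift_to_loss)
    n_seg <- min(vapply(prof, nrow, 0L))
    if (n_seg >= 4) {
      mat <- vapply(prof, function(p) p$loss_da[seq_len(n_seg)],
                    numeric(n_seg))
      mean_losses <- rowMeans(as.matrix(mat))
      # segment 1 is the drift reference (zero by construction)
      decay <- tryCatch(fit_decay_model(mean_losses[-1],
                                        k = seq_len(n_seg - 1)),
                        error = function(e) NULL)
    }
  }
  list(centroids = cents, traces = traces, losses = losses,
       decay_fit = decay, plan = plan)
}
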