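test_that("segment plans cover the transient with the requested overlap", {
  p <- plan_segments(1, 15, 0.5)
  expect_equal(nrow(p), 15)
  expect_equal(unique(p$length), 0.125)
  expect_equal(p$start[15] + p$length[1], 1)       # exact coverage
  expect_true(all(diff(p$start) > 0))
  p0 <- plan_segments(2, 8, 0)                     # contiguous tiling
  expect_equal(unique(p0$length), 0.25)
  expect_equal(p0$start, seq(0, 1.75, by = 0.25))
  expect_error(plan_segments(1, 1, 0.5), class = "freqchase_invalid")
  expect_error(plan_segments(1, 15, 1), class = "freqchase_invalid")
})

test_that("a stable ion gives one consistent centroid per segment", {
  m <- fast_model()
  tr <- simulate_transient(list(std_ion()), m, noise_sigma = 1,
                           duration = 1, seed = 21)
  cents <- segmented_centroids(tr, plan_segments(1, 15, 0.5), m,
                               mz_range = c(21000, 21700))
  expect_equal(nrow(cents), 15)
  expect_equal(sort(cents$segment_index), 1:15)
  # intensity constant within 5% of the charge-calibrated height
  expect_true(all(abs(cents$intensity - 150 / 175) < 0.05 * 150 / 175))
  expect_lt(max(cents$mz) - min(cents$mz), 1)
})

test_that("an ion absent from the late transient is only seen early", {
  m <- fast_model()
  first <- simulate_transient(list(std_ion()), m, noise_sigma = 1,
                              duration = 0.5, seed = 22)
  rest <- simulate_transient(list(), m, noise_sigma = 1, duration = 0.5,
                             seed = 23)
  full <- freqchase:::new_transient(c(first$samples, rest$samples),
                                    m$sample_rate)
  cents <- segmented_centroids(full, plan_segments(1, 15, 0.5), m,
                               mz_range = c(21000, 21700))
  plan <- plan_segments(1, 15, 0.5)
  late <- plan$segment_index[plan$start >= 0.5]
  expect_true(all(!cents$segment_index %in% late))
  expect_true(any(cents$segment_index <= 5))
})

test_that("close centroid pairs are dropped symmetrically, lone ions kept", {
  df <- data.frame(mz = c(21000, 21001, 22000), frequency_hz = 0,
                   intensity = 0.8, fwhm_th = 2, snr = 50,
                   segment_index = 1L)
  out <- isolate_candidates(df, min_separation_bins = 2)
  expect_equal(out$mz, 22000)   # both members of the close pair removed
  lone <- isolate_candidates(df[3, ], min_separation_bins = 2)
  expect_equal(nrow(lone), 1)
})

test_that("tracing chains stable, drifting and well-separated ions correctly", {
  m <- fast_model()
  # single stable ion -> one full-length trace
  tr <- simulate_transient(list(std_ion()), m, noise_sigma = 1,
                           duration = 1, seed = 24)
  res <- chase_transient(tr, m, mz_range = c(21000, 21700))
  expect_equal(length(res$traces), 1)
  expect_equal(nrow(res$traces[[1]]$centroids), 15)
  expect_equal(res$traces[[1]]$classification, "stable")
  # two ions 100 Th apart -> two disjoint traces
  tr2 <- simulate_transient(
    list(std_ion(), ion_spec((21333.33 + 100) * 149, 149, phase0 = 2)),
    m, noise_sigma = 1, duration = 1, seed = 25)
  res2 <- chase_transient(tr2, m, mz_range = c(21000, 21700))
  expect_equal(length(res2$traces), 2)
  rows <- unlist(lapply(res2$traces, function(t) t$centroids$mz))
  expect_equal(length(rows), 30)   # no centroid shared between traces
  means <- sort(vapply(res2$traces, function(t) mean(t$centroids$mz), 0))
  expect_equal(means, c(21333.33, 21433.33), tolerance = 1e-4)
  # drifting ion (~1.5 Th over the transient) chained into one trace
  z <- 150
  lp <- loss_process(linear_rate = z * 1.5 / 15, exp_amplitude = 0,
                     stochastic = FALSE)
  tr3 <- simulate_transient(list(std_ion(loss = lp)), m, noise_sigma = 1,
                            duration = 1, seed = 26)
  res3 <- chase_transient(tr3, m, mz_range = c(21000, 21700))
  expect_equal(length(res3$traces), 1)
  # window centres span 87.5% of the transient, so the chased drift is
  # ~1.31 of the 1.5 Th generated drift
  drift <- diff(range(res3$traces[[1]]$centroids$mz))
  expect_lt(abs(drift - 1.3125), 0.3)
})

test_that("traces bridge a single missing segment but not more", {
  mk <- function(segs) {
    df <- data.frame(mz = 21333.3, frequency_hz = 56400, intensity = 0.85,
                     fwhm_th = 0.5, snr = 50, segment_index = segs)
    trace_ions(df, n_segments = 15)
  }
  bridged <- mk(c(1:7, 9:15))                        # one gap bridged
  expect_equal(length(bridged), 1)
  expect_equal(nrow(bridged[[1]]$centroids), 14)
  # a 3-segment hole splits the trace; both fragments fall below the
  # 60% minimum length and are discarded
  expect_equal(length(mk(c(1:5, 9:15))), 0)
})

test_that("stability filtering applies the 4 Th / 0.2 thresholds", {
  stable <- make_trace(rep(21343.1, 10))
  noisy_mz <- make_trace(21343.1 + c(rep(-6, 5), rep(6, 5)))   # sd > 4
  noisy_int <- make_trace(rep(21343.1, 10),
                          intensity = 0.85 + c(rep(-0.26, 5), rep(0.26, 5)))
  out <- filter_traces(list(stable, noisy_mz, noisy_int))
  expect_true(is.na(out[[1]]$classification))
  expect_equal(out[[2]]$classification, "rejected")
  expect_equal(out[[3]]$classification, "rejected")
  # charge-loss traces are exempt from the m/z std filter
  jump <- make_trace(c(rep(21343.1, 5), rep(21492.35, 5)))
  jump$classification <- "charge_loss"
  expect_equal(filter_traces(list(jump))[[1]]$classification, "charge_loss")
})

test_that("traces classify as stable, gradual loss or charge loss", {
  m <- instrument_model()
  # zero drift -> stable
  tr <- classify_trace(make_trace(rep(21343.1, 15)), 1, m)
  expect_equal(tr$classification, "stable")
  # monotone 3-bin drift -> gradual loss (bin = full-transient Fourier bin)
  bin_mz <- 2 * 21343.1 * (1 / 4) / mz_to_freq(21343.1, m)
  drift <- classify_trace(
    make_trace(21343.1 - seq(0, 3 * bin_mz, length.out = 15)), 1, m)
  expect_equal(drift$classification, "gradual_loss")
  # z = 144 quantized jump -> charge loss with the right charge
  jump <- classify_trace(
    make_trace(c(rep(21343.1, 8), rep(21343.1 * 144 / 143, 7))), 1, m)
  expect_equal(jump$classification, "charge_loss")
  expect_equal(jump$assigned_charge, 144)
  expect_equal(jump$detail$z_estimate, 144, tolerance = 1e-6)
  # a large jump matching no integer spacing is flagged, not guessed
  odd <- classify_trace(
    make_trace(c(rep(21343.1, 8), rep(21343.1 * 1.003, 7))), 1, m)
  expect_equal(odd$classification, "rejected")
  expect_true("ambiguous_jump" %in% odd$flags)
  # rejected traces are not classified
  rej <- make_trace(rep(21343.1, 10)); rej$classification <- "rejected"
  expect_error(classify_trace(rej, 1, m), class = "freqchase_invalid")
})

test_that("frequency drift converts to neutral loss and sums exactly", {
  flat <- drift_to_loss(make_trace(rep(21343.1, 10)), charge = 100)
  expect_true(all(flat$loss_da == 0))
  two <- drift_to_loss(make_trace(c(21343.1, 21343.1 - 1.57)), charge = 100)
  expect_equal(two$loss_da[2], 157)
  mz <- 21343.1 - cumsum(c(0, runif(9, 0, 0.3)))
  prof <- drift_to_loss(make_trace(mz), charge = 137)
  expect_equal(prof$cumulative_da, cumsum(prof$loss_da))
  expect_equal(prof$cumulative_da[10], 137 * (mz[1] - mz[10]))
  expect_error(drift_to_loss(make_trace(mz)), class = "freqchase_invalid")
})

test_that("decay model recovers its parameters and flags degeneracy", {
  lp <- loss_process(25, 120, 3)
  tab <- simulate_segment_losses(lp, 15, 1000, seed = 7)
  fit <- fit_decay_model(colMeans(tab))
  expect_gte(fit$r2, 0.998)
  expect_equal(fit$alpha, 25, tolerance = 0.1)
  expect_equal(fit$beta, 120, tolerance = 0.1)
  # asymptote of the fitted curve is the linear term
  k_inf <- fit$alpha + fit$beta * exp(-(1e6 - 1) / fit$tau)
  expect_equal(k_inf, fit$alpha)
  # beta = 0 data: alpha recovered, tau flagged unidentifiable
  tab0 <- simulate_segment_losses(loss_process(25, 0, 3), 15, 1000,
                                  seed = 8)
  fit0 <- fit_decay_model(colMeans(tab0))
  expect_equal(fit0$alpha, 25, tolerance = 0.02)
  expect_true("tau_unidentifiable" %in% fit0$flags)
  expect_true(fit0$r2 >= 0 && fit0$r2 <= 1)
  expect_error(fit_decay_model(1:3), class = "freqchase_invalid")
})

test_that("charge-loss doublets give direct charge and mass", {
  est <- charge_from_pair(99, 100)
  expect_equal(est$z_estimate, 100)
  ev <- charge_loss_event(99, 100)
  mp <- mass_from_pair(ev, subtract_proton = FALSE)
  expect_equal(mp$mass, 9900)
  # the printed single-ion example: z = 144 at m/z 21,343.1
  est2 <- charge_from_pair(21343.1, 21492.35)
  expect_equal(est2$z_estimate, 144, tolerance = 1e-4)
  ev2 <- charge_loss_event(21343.1, 21492.35, 0.1, 0.1)
  mp2 <- mass_from_pair(ev2, instrument_model(), subtract_proton = TRUE)
  expect_equal(mp2$mass, 144 * (21343.1 - 1.00728), tolerance = 1e-9)
  # uncertainty scales linearly with the centroid uncertainty
  ev_big <- charge_loss_event(21343.1, 21492.35, 0.2, 0.2)
  expect_equal(mass_from_pair(ev_big)$uncertainty / mp2$uncertainty, 2,
               tolerance = 1e-6)
  expect_error(charge_from_pair(100, 99), class = "freqchase_invalid")
  expect_warning(mass_from_pair(charge_loss_event(100, 250)),
                 "integer")
})

test_that("mirrored sidebands of radial modulation are detected and scored", {
  m <- fast_model()
  tr <- simulate_transient(
    list(std_ion(radial_freq = 800, radial_depth = 0.1)),
    m, noise_sigma = 1, duration = 0.5, seed = 12)
  sp <- compute_spectrum(tr, m)
  main <- main_peak(pick_peaks(sp, model = m))
  sb <- detect_radial_sidebands(sp, main, search_width = 2000, model = m)
  expect_true(sb$found)
  expect_equal(sb$upper_offset_hz, 800, tolerance = sp$df / 800)
  expect_equal(sb$lower_offset_hz, 800, tolerance = sp$df / 800)
  expect_gte(sb$mirror_symmetry_score, 0.9)
  # no modulation -> no sidebands, and that is not an error
  tr0 <- simulate_transient(list(std_ion()), m, noise_sigma = 1,
                            duration = 0.5, seed = 13)
  sp0 <- compute_spectrum(tr0, m)
  main0 <- main_peak(pick_peaks(sp0, model = m))
  sb0 <- detect_radial_sidebands(sp0, main0, search_width = 2000,
                                 model = m)
  expect_false(sb0$found)
})

test_that("retained traces map one-to-one onto true ions", {
  m <- fast_model()
  set.seed(31)
  n_match <- 0; n_traces <- 0
  for (rep in 1:12) {
    # two well-separated ions per scan, mixed behaviours
    mz1 <- runif(1, 21100, 21400)
    mz2 <- mz1 + runif(1, 150, 250)
    lp <- loss_preset("small")
    ions <- list(ion_spec(mz1 * 150, 150, phase0 = runif(1, 0, 6),
                          loss = lp),
                 ion_spec(mz2 * 145, 145, phase0 = runif(1, 0, 6)))
    tr <- simulate_transient(ions, m, noise_sigma = 1, duration = 1,
                             seed = 400 + rep)
    res <- chase_transient(tr, m, mz_range = c(20900, 21900))
    truths <- c(mz1, mz2)
    for (t in res$traces) {
      if (identical(t$classification, "rejected")) next
      n_traces <- n_traces + 1
      d <- abs(mean(t$centroids$mz) - truths)
      if (min(d) < 2) n_match <- n_match + 1
      # no trace mixes two true ions: its spread is far below the spacing
      expect_lt(diff(range(t$centroids$mz)), 50)
    }
  }
  expect_gte(n_traces, 20)
  expect_gte(n_match / n_traces, 0.95)
})
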