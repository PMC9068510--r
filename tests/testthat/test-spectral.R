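# Construct an ion_spectrum by hand for grid-level operations
synthetic_spectrum <- function(magnitude, df = 1, fs = 1000) {
  structure(list(frequency = (seq_along(magnitude) - 1) * df,
                 magnitude = magnitude, mode = "magnitude",
                 sample_rate = fs, n_samples = length(magnitude),
                 zero_pad_factor = 1L,
                 effective_duration = 1 / df, df = df),
            class = "ion_spectrum")
}

test_that("peak height is duration-invariant (normalization contract)", {
  m <- fast_model()
  unit_ion <- ion_spec(3.2e6, 175)  # amplitude z / gain = 1.0
  for (d in c(0.5, 1, 2)) {
    tr <- simulate_transient(list(unit_ion), m, noise_sigma = 0,
                             duration = d, seed = 1)
    sp <- compute_spectrum(tr, m)
    pk <- pick_peaks(sp, model = m)
    expect_equal(main_peak(pk)$intensity, 1.0, tolerance = 0.01)
  }
})

test_that("frequency axis spacing is fs / (N x pad)", {
  tr <- simulate_transient(list(), instrument_model(), noise_sigma = 0,
                           duration = 1, seed = 1)
  sp <- compute_spectrum(tr, instrument_model())
  expect_equal(sp$df, 0.25)  # 250 kHz, 1 s, pad 4
  expect_equal(diff(sp$frequency[1:2]), 0.25)
  expect_true(all(sp$magnitude == 0))  # all-zero input stays zero
})

test_that("spectra of fewer than two samples are refused", {
  tr <- simulate_transient(list(), fast_model(), noise_sigma = 0,
                           duration = 0.01, seed = 1)
  tr$samples <- tr$samples[1]
  expect_error(compute_spectrum(tr, fast_model()),
               class = "freqchase_invalid")
})

test_that("parabola centroid respects symmetry and bounds", {
  sp <- synthetic_spectrum(c(0, 0.1, 0.5, 1, 0.5, 0.1, 0))
  ct <- centroid_parabola(sp, 4, noise_sd = 0.01)
  expect_equal(ct$frequency_hz, sp$frequency[4])  # symmetric flanks
  expect_gte(ct$intensity, sp$magnitude[4])       # vertex >= centre bin
  asym <- synthetic_spectrum(c(0, 0.2, 0.9, 1, 0.3, 0.05, 0))
  ct2 <- centroid_parabola(asym, 4)
  expect_gte(ct2$intensity, asym$magnitude[4])
  expect_lt(ct2$frequency_hz, asym$frequency[4])  # pulled toward heavier side
  expect_error(centroid_parabola(sp, 1), class = "freqchase_invalid")
  expect_error(centroid_parabola(sp, 7), class = "freqchase_invalid")
})

test_that("off-grid frequencies are centroided within 0.05 Fourier bin", {
  m <- fast_model()
  # dense-DTFT oracle: argmax of |sum x e^{-2pi i f t}| on a fine grid
  dtft_peak <- function(x, fs, f_lo, f_hi) {
    t <- (seq_along(x) - 1) / fs
    fgrid <- seq(f_lo, f_hi, length.out = 2001)
    mags <- vapply(fgrid, function(f)
      Mod(sum(x * exp(-2i * pi * f * t))), 0)
    fgrid[which.max(mags)]
  }
  for (frac in c(0.13, 0.37, 0.5)) {
    # place the ion frac padded-bins off the grid
    dur <- 0.25
    df <- 1 / (dur * 4)
    f_target <- 56000 + frac * df
    mass <- 150 * freq_to_mz(f_target, m)
    tr <- simulate_transient(list(ion_spec(mass, 150)), m, noise_sigma = 0,
                             duration = dur, seed = 1)
    sp <- compute_spectrum(tr, m)
    pk <- main_peak(pick_peaks(sp, model = m))
    expect_lt(abs(pk$frequency_hz - f_target) / sp$df, 0.05)
    oracle <- dtft_peak(tr$samples, m$sample_rate, f_target - 2,
                        f_target + 2)
    expect_lt(abs(pk$frequency_hz - oracle) / sp$df, 0.06)
  }
})

test_that("peak picking controls false positives and finds separated ions", {
  m <- fast_model()
  # noise-only spectra at threshold 10: expect no detections
  hits <- 0
  for (s in 1:3) {
    tr <- simulate_transient(list(), m, noise_sigma = 2, duration = 0.2,
                             seed = s)
    hits <- hits + nrow(pick_peaks(compute_spectrum(tr, m),
                                   snr_threshold = 10, model = m))
  }
  expect_equal(hits, 0)
  # two ions 500 Th apart -> exactly two centroids
  tr2 <- simulate_transient(
    list(std_ion(), ion_spec(21833.33 * 140, 140, phase0 = 1)),
    m, noise_sigma = 1, duration = 0.25, seed = 4)
  pk <- pick_peaks(compute_spectrum(tr2, m), model = m)
  expect_equal(nrow(pk), 2)
  expect_equal(sort(pk$mz), c(21333.33, 21833.33), tolerance = 1e-4)
  # an empty m/z window is not an error
  expect_equal(nrow(pick_peaks(compute_spectrum(tr2, m), model = m,
                               mz_range = c(100, 101))), 0)
})

test_that("resolution grows linearly with duration and halves in m/z domain", {
  m <- fast_model()
  R <- numeric(2)
  for (i in 1:2) {
    d <- c(0.25, 0.5)[i]
    tr <- simulate_transient(list(std_ion()), m, noise_sigma = 0,
                             duration = d, seed = 1)
    sp <- compute_spectrum(tr, m)
    pk <- main_peak(pick_peaks(sp, model = m))
    res <- fwhm_resolution(sp, pk)
    expect_false(res$flagged)
    expect_gt(res$R, 0)
    # f ~ (m/z)^(-1/2) => R in m/z domain is half the frequency-domain R
    expect_equal(res$R_freq / res$R, 2, tolerance = 0.02)
    R[i] <- res$R
  }
  expect_equal(R[2] / R[1], 2, tolerance = 0.05)
})

test_that("noise-band sigma is consistent across seeds and guards peaks", {
  m <- fast_model()
  sds <- vapply(1:2, function(s) {
    tr <- simulate_transient(list(), m, noise_sigma = 2, duration = 0.25,
                             seed = s)
    noise_band_sigma(compute_spectrum(tr, m), c(25000, 32000), m)
  }, 0)
  expect_equal(sds[1], sds[2], tolerance = 0.1)
  # zero-noise transient: sigma is exactly zero
  tr0 <- simulate_transient(list(), m, noise_sigma = 0, duration = 0.1,
                            seed = 1)
  expect_equal(as.numeric(
    noise_band_sigma(compute_spectrum(tr0, m), c(25000, 32000), m)), 0)
  # a window containing an ion is refused
  tri <- simulate_transient(list(std_ion()), m, noise_sigma = 1,
                            duration = 0.25, seed = 3)
  expect_error(noise_band_sigma(compute_spectrum(tri, m),
                                c(21000, 21700), m),
               class = "freqchase_invalid")
})

test_that("power-law fitting recovers exact and degenerate cases", {
  x <- c(1, 2, 4, 8, 16)
  fit <- fit_power_law(x, 4 * x^-0.5)
  expect_equal(fit$A, 4)
  expect_equal(fit$B, -0.5)
  expect_equal(fit$r2, 1)
  flat <- fit_power_law(x, rep(3, 5))
  expect_equal(flat$B, 0)
  expect_error(fit_power_law(x, c(1, 2, -3, 4, 5)),
               class = "freqchase_invalid")
  expect_error(fit_power_law(1:2, 1:2), class = "freqchase_invalid")
})
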