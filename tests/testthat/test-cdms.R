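test_that("intensity converts to charge through the gain factor", {
  m <- instrument_model()
  expect_equal(intensity_to_charge(1, m), 175)
  expect_equal(intensity_to_charge(0, m), 0)
  expect_error(intensity_to_charge(-0.1, m), class = "freqchase_invalid")
  # closure: simulate -> spectrum -> charge recovers the true charge
  fm <- fast_model()
  tr <- simulate_transient(list(std_ion()), fm, noise_sigma = 1,
                           duration = 0.5, seed = 41)
  sp <- compute_spectrum(tr, fm)
  pk <- main_peak(pick_peaks(sp, model = fm))
  sig <- noise_band_sigma(sp, c(25000, 32000), fm)
  z <- intensity_to_charge(pk$intensity, fm)
  expect_lt(abs(z - 150), 3 * sig)
  expect_lt(abs(z - 150) / 150, 0.01)   # < 1% bias at this S/N
})

test_that("drift correction recovers what split-peak filtering rejects", {
  m <- fast_model()
  z <- 150
  # stable ion: drift-corrected result matches the direct centroid
  trs <- simulate_transient(list(std_ion()), m, noise_sigma = 1,
                            duration = 1, seed = 42)
  res_s <- chase_transient(trs, m, mz_range = c(21000, 21700))
  ion_s <- drift_correct(res_s$traces[[1]], m)
  sp_s <- compute_spectrum(trs, m)
  pk_s <- main_peak(pick_peaks(sp_s, model = m))
  expect_equal(ion_s$intensity, pk_s$intensity, tolerance = 0.01)
  expect_equal(ion_s$mz, pk_s$mz, tolerance = 1e-5)
  # drifting ion (5 Hz, i.e. 5 peak-widths over 1 s, 20 Fourier bins):
  # the direct peak collapses and is rejected, while segment averaging
  # restores >= 90% of the reference height
  mz0 <- 3.2e6 / z
  dmz <- 2 * mz0 * 5 / mz_to_freq(mz0, m)
  lp <- loss_process(linear_rate = z * dmz / 15, exp_amplitude = 0,
                     stochastic = FALSE)
  trd <- simulate_transient(list(std_ion(loss = lp)), m, noise_sigma = 1,
                            duration = 1, seed = 43)
  sp_d <- compute_spectrum(trd, m)
  pk_d <- pick_peaks(sp_d, model = m, mz_range = c(21000, 21700))
  flt <- filter_split_peaks(sp_d, pk_d, m)
  expect_false(any(flt$accepted))
  expect_lt(max(pk_d$intensity), 0.9 * z / 175)
  res_d <- chase_transient(trd, m, mz_range = c(21000, 21700))
  ion_d <- drift_correct(res_d$traces[[1]], m)
  expect_gte(ion_d$intensity, 0.9 * z / 175)
  ct <- res_d$traces[[1]]$centroids
  expect_true(ion_d$mz >= min(ct$mz) && ion_d$mz <= max(ct$mz))
  # rejected traces cannot be drift-corrected
  bad <- res_d$traces[[1]]; bad$classification <- "rejected"
  expect_error(drift_correct(bad, m), class = "freqchase_invalid")
})

test_that("split-peak filtering keeps clean and borderline-drift peaks", {
  m <- fast_model()
  keep_fraction <- function(drift_hz, seed) {
    z <- 150; mz0 <- 3.2e6 / z
    dmz <- 2 * mz0 * drift_hz / mz_to_freq(mz0, m)
    lp <- if (drift_hz > 0)
      loss_process(linear_rate = z * dmz / 15, exp_amplitude = 0,
                   stochastic = FALSE) else NULL
    tr <- simulate_transient(list(std_ion(loss = lp)), m, noise_sigma = 1,
                             duration = 1, seed = seed)
    sp <- compute_spectrum(tr, m)
    pk <- pick_peaks(sp, model = m, mz_range = c(21000, 21700))
    flt <- filter_split_peaks(sp, pk, m)
    flt$accepted[which.max(flt$intensity)]
  }
  expect_true(keep_fraction(0, 44))      # clean sinusoid accepted
  expect_true(keep_fraction(0.125, 45))  # 0.5 Fourier bin: within margin
  expect_false(keep_fraction(5, 46))     # several peak widths: split
})

test_that("mass histograms resolve the two capsid modes", {
  set.seed(47)
  masses <- c(rnorm(300, 3e6, 1.2e4), rnorm(300, 4e6, 1.2e4))
  ions <- data.frame(mass = masses)
  h <- build_mass_histogram(ions, bin_width = 1e4)
  expect_equal(sum(h$counts), 600)
  expect_equal(nrow(h$modes), 2)
  expect_equal(sort(h$modes$mass), c(3e6, 4e6), tolerance = 1e-2)
  expect_true(all(h$modes$resolution > 0))
  # modes stay put under bin-width halving
  h2 <- build_mass_histogram(ions, bin_width = 5e3)
  expect_equal(sort(h2$modes$mass), sort(h$modes$mass), tolerance = 5e-3)
  expect_error(build_mass_histogram(data.frame(mass = numeric(0)), 1e4),
               class = "freqchase_invalid")
})

test_that("survival ratio tracks when the ion disappears", {
  m <- fast_model()
  glue <- function(a, b) freqchase:::new_transient(c(a$samples, b$samples),
                                                   m$sample_rate)
  ion_part <- function(dur, seed) simulate_transient(list(std_ion()), m,
                                                     noise_sigma = 0.5,
                                                     duration = dur,
                                                     seed = seed)
  noise_part <- function(dur, seed) simulate_transient(list(), m,
                                                       noise_sigma = 0.5,
                                                       duration = dur,
                                                       seed = seed)
  mz <- 3.2e6 / 150
  full <- ion_part(1, 48)
  expect_equal(survival_ratio(full, mz, m), 1, tolerance = 0.05)
  half <- glue(ion_part(0.5, 49), noise_part(0.5, 50))
  expect_lt(survival_ratio(half, mz, m), 0.1)
  threeq <- glue(ion_part(0.75, 51), noise_part(0.25, 52))
  expect_equal(survival_ratio(threeq, mz, m), 0.5, tolerance = 0.1)
  # undetectable first half is an error
  expect_error(survival_ratio(noise_part(1, 53), mz, m),
               class = "freqchase_invalid")
})

test_that("charge sigma scaling flags degenerate noiseless input", {
  res <- charge_sigma_vs_time(list(rep(150, 5), rep(150, 5), rep(150, 5)),
                              c(0.5, 1, 2))
  expect_true(res$degenerate)
  expect_null(res$fit)
  expect_error(charge_sigma_vs_time(list(1:2), 1),
               class = "freqchase_invalid")
})

test_that("sampling reports track utilization and fold gain", {
  r0 <- sampling_report(100, 0, 0)
  expect_equal(r0$fold_improvement, 1)
  expect_equal(r0$utilization_direct, 1)
  r <- sampling_report(15, 985, 330)
  expect_equal(r$utilization_direct, 0.015)
  expect_equal(r$utilization_corrected, 0.345)
  expect_equal(r$fold_improvement, 23)
  expect_error(sampling_report(10, 5, 6), class = "freqchase_invalid")
})
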