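# A reduced-rate instrument keeps FFT sizes small in unit tests; all ions
# used with it sit at m/z > 21,000 (axial frequency < 56.5 kHz, well below
# the 65.5 kHz Nyquist limit).
fast_model <- function(...) instrument_model(sample_rate = 131072, ...)

# z = 150 ion at m/z 21,333.3 (3.2 MDa particle)
std_ion <- function(...) ion_spec(3.2e6, 150, ...)

# Build an ion_trace directly from m/z / intensity series (bypassing the
# spectral layer) for tests of the trace-level operations.
make_trace <- function(mz, intensity = rep(0.85, length(mz)),
                       segments = seq_along(mz),
                       model = instrument_model()) {
  df <- data.frame(mz = mz, frequency_hz = mz_to_freq(mz, model),
                   intensity = intensity, fwhm_th = 0.5, snr = 50,
                   segment_index = segments)
  freqchase:::new_ion_trace(df, trace_id = 1L)
}

main_peak <- function(centroids) centroids[which.max(centroids$intensity), ]
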