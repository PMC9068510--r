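---
title: "Frequency chasing for single-ion Orbitrap CDMS: models and methods"
author: "freqchase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency chasing for single-ion Orbitrap CDMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freqchase)
```

## The measurement problem

In Orbitrap-based charge-detection mass spectrometry (CDMS), individual
megadalton ions — virus capsids, engineered nanocages, antibody oligomers —
are trapped one at a time and detected through the image current they induce
while oscillating along the central electrode. Two facts make single-particle
mass analysis possible:

* the axial oscillation frequency depends only on m/z,
  $f = c \,(m/z \,/\, 1000)^{-1/2}$ with the calibration coefficient
  $c = 0.26055$ MHz for m/z in kilothomson, and
* the peak height of the ion's signal in a normalized magnitude spectrum is
  proportional to its charge $z$ (here, 175 charges per unit intensity).

A single ion therefore yields a charge (from intensity) and an m/z (from
frequency), hence a mass $m = z \times m/z$ per particle. The difficulty is
that the ion is not a fixed-frequency oscillator. Over a multi-second
transient it travels kilometres through residual gas, sheds residual solvent
(mass down, frequency up), and occasionally loses a single elementary charge
(m/z up, frequency down). Any frequency drift beyond one Fourier bin smears
the ion's peak into a split shape, destroying both the charge and the m/z
readout for that ion.

"Frequency chasing" is the remedy: divide the transient into overlapping
windows, centroid each window's spectrum, chain the centroids of each ion
through time, classify its behaviour, and either convert the drift into a
per-segment neutral-loss record, recover the ion for CDMS by averaging its
per-segment intensities and m/z values, or — for the rare charge-stripping
doublets — compute charge and mass directly from the size of the quantized
jump, with no intensity calibration at all.

## What the simulator emulates

`simulate_transient()` synthesizes the image current as a sum of ion terms
$a_i(t)\cos\phi_i(t)$ plus white Gaussian detector noise:

* **Frequency law.** The instantaneous frequency follows the instrument law
  at the ion's current m/z; the phase is the running integral of frequency
  and stays continuous through every event.
* **Charge-calibrated amplitude.** Amplitudes are set so that a
  non-decaying ion's normalized spectral peak height equals
  `charge / charge_gain`. This closes the loop with
  `intensity_to_charge()`: the calibration factor is exact by construction,
  as it is (after empirical calibration) on the instrument.
* **Neutral loss.** Losses are discrete events. The expected loss in
  segment $k$ (1-based) is $\alpha + \beta e^{-(k-1)/\tau}$: a constant
  term from collisions at a fixed rate per travelled distance during
  detection, plus an exponentially relaxing term from the sudden
  collisional activation the ion acquires during injection. Event counts
  are Poisson with mean (expected loss)/(mean event mass); per-event masses
  are Normal, truncated at zero (water-like 18 ± 2 Da, or heavier ~77 Da
  adducts). A deterministic mode applies the expectation exactly for exact
  tests. The continuous-time event rate used inside the simulator is the
  closed-form density whose segment integrals reproduce the per-segment
  expectations.
* **Charge stripping.** At a configurable time the charge drops by one,
  the amplitude scales by $(z-1)/z$, and m/z becomes $m/(z-1)$. Whether
  the departing charge carries a proton's mass is configurable
  (default yes); the two options differ by ~1 Da in 3 MDa.
* **Radial motion.** Modelled as pure amplitude modulation at the radial
  frequency, which produces the observed phenomenology: a mirrored pair of
  sidebands above and below the axial peak. Frequency modulation is not
  simulated.
* **Noise.** White Gaussian time-domain noise only. The default
  `noise_sigma = 2` puts a z = 150 ion at a spectral S/N of roughly 150 per
  second of transient, reaching several hundred at 4 s — the regime of real
  single-ion recordings. There is no 1/f component, electronic ringing, or
  harmonic structure, so tests passing here say nothing about those
  artefacts on real data.

Not emulated: space charge and ion–ion interaction, image-charge geometry,
C-trap injection dynamics beyond the exponential activation term, or any
dependence of detected amplitude on ion energy/radius (a per-ion
`amp_scale` stands in for the energy acceptance spread).

## Spectral processing choices

* **Zero padding and magnitude mode.** Transients are zero-padded fourfold
  before the FFT and analysed in magnitude mode. Magnitudes are normalized
  by $N/2$ so peak height is duration-invariant (the contract behind the
  charge calibration). The frequency axis spacing — one "Fourier bin"
  throughout this package — is `sample_rate / (N × 4)`; the natural
  resolution (peak width) is four bins.
* **Centroids.** Three-point least-squares parabola through the peak bin
  and neighbours on linear magnitudes. On the fourfold-padded grid its
  worst-case bias is ~0.006 bins, comfortably inside the 0.05-bin
  accuracy the analysis assumes.
* **The absorption surrogate.** Proprietary phase-aware ("enhanced") FT
  processing is not public. `compute_spectrum(mode =
  "absorption_surrogate")` phase-rotates the spectrum by a known initial
  phase and takes the real part, giving sharper peaks for simulated data;
  magnitude mode is the default analysis path and the only one applicable
  when the phase is unknown. No equivalence with the proprietary
  processing is claimed.
* **Peak picking.** Local maxima above an SNR threshold times a robust
  (median-based, Rayleigh-consistent) noise SD. Because an unwindowed
  sinusoid's sidelobes reach 21.7% of the main peak, candidates that sit
  below 1.2× the Dirichlet sidelobe envelope of an already-accepted
  stronger peak (plus 3 noise SD) are vetoed. Genuine satellites of split
  peaks rise above this envelope and survive. No apodization is applied by
  default, matching the processing the analysis emulates.
* **FWHM.** Half-height crossings by linear interpolation on the padded
  grid. Since $f \propto (m/z)^{-1/2}$, resolving power in the m/z domain
  is half the frequency-domain value; both are reported.

## Chasing, classification and the decision points

Defaults: 15 segments per second with 50% overlap (window length
`duration / ((n+1)/2)`), greedy nearest-in-m/z chaining in order of
decreasing trace intensity, matching window 1% of m/z (wide enough for a
single-charge-loss jump at megadalton charge states), at most one bridged
missing segment, minimum trace length 60% of the segments, and isolation
of any centroid with a same-segment neighbour within 2 segment-FWHMs (both
members dropped, which also prevents tracing through crossing ions).

Classification works on the chained m/z series:

* **stable** — total excursion below one full-transient Fourier bin
  (converted to m/z units at the trace position);
* **charge_loss** — a single upward jump at least 3 bins tall whose size
  matches the $z/(z-1)$ spacing of an integer charge within
  max(0.3, 3× propagated uncertainty). Side positions are medians over up
  to five segments per side and the scatter estimate is MAD-based: the
  window that contains the frequency step yields interference-biased
  centroids next to the jump, and plain means were measurably corrupted
  by them;
* **gradual_loss** — everything else. Large jumps matching no integer
  spacing are flagged `ambiguous_jump` and rejected, not guessed.

Two design points deserve justification because the obvious ordering fails:

* **Classify before the stability filter.** The 4 Th / 0.2 standard
  deviation filters exist to select traces whose segment averages are
  meaningful. A charge-loss trace has an m/z SD of ~75 Th from its jump
  alone and would always be discarded; it is classified first and exempted,
  feeding the direct doublet path instead of segment averaging.
* **Doublet pairing.** The segment that contains the frequency step shows
  neither clean peak but an interference comb; the isolation filter then
  removes everything in that segment, and the chain can break into a
  before-fragment and an after-fragment, each too short to survive the
  length filter. `trace_ions()` therefore rejoins time-disjoint, internally
  coherent fragments whose m/z offset matches an integer-$z$ jump — the
  doublet signature itself — before applying the length filter. Pairing
  tolerance is deliberately loose (|z − round(z)| < 0.35) because the final
  charge assessment is re-derived by `classify_trace()`/
  `charge_from_pair()`; the loose gate can in principle pair two unrelated
  ions that hand over within a few segments of each other, a known
  limitation shared with any automated doublet search.

With the charge known (assigned from intensity × gain for gradual traces),
drift converts to neutral loss as $-z\,\Delta(m/z)$ per segment step, and
the ensemble-mean per-segment losses are fitted with
$\alpha + \beta e^{-(k-1)/\tau}$ by bounded Levenberg–Marquardt
(`minpack.lm`). When the fitted exponential's decay across the observed
segments does not exceed twice the residual scatter the model is
unidentifiable in $\tau$; the fit falls back to the constant term and says
so, rather than reporting an arbitrary time constant.

For charge-loss doublets, `mass_from_pair()` uses
$m = \mathrm{round}(z) \times (m/z_{\text{before}} - m_p)$; the proton
subtraction is a flag because the convention cannot be pinned down to the
last dalton at megadalton scale, where the correction (~150 Da in 3 MDa)
is far below the centroiding uncertainty anyway.

## CDMS recovery and bookkeeping

`filter_split_peaks()` rejects full-transient centroids with satellite
maxima exceeding the clean-peak sidelobe envelope by 20% of the main
height within ±10 bins, or with FWHM above 1.5× the theoretical
1.2067/T. Drifts inside the one-bin stability margin pass. `drift_correct()`
averages per-segment intensities and m/z values of retained traces — the
per-window drift is small relative to the *segment* Fourier bin, so the
segment peak heights are unaffected even when the full-transient peak has
collapsed — and rebuilds charge and mass from the averages.
`sampling_report()` does the utilization arithmetic (e.g. a 1.5% direct
utilization recovered to 34.5% is the 23-fold figure of merit);
the achievable fold-change is entirely data-dependent.

Histogram modes are fitted with an iterative Gaussian (±3σ window);
resolution is reported as mass/FWHM. Charge is kept real-valued for
histograms and also rounded for reporting.

## Collision physics

Path length is duration × frequency × 93.7425 mm per oscillation (an
instrument-averaged constant; no trajectory integration). CCS is hard-sphere
$\pi(r_i + r_n)^2$ with user-supplied radii. Gas number density comes from
the cold-cathode gauge read-out via the ideal gas law (1 mbar = 100 Pa
exactly, CODATA $k_B$), doubled for the true trap pressure and corrected
for gauge sensitivity when the gas is xenon (relative sensitivity 2.4,
configurable — gauge manuals give 2–3). Expected collisions are path length
over mean free path, exactly linear in duration and pressure. The
mass-scaling profile assumes $z \propto m^{1/2}$ (Rayleigh-like native-ESI
charging, exponent configurable), constant particle density
($\mathrm{CCS} \propto m^{2/3}$), and lab collision energy proportional to
charge; energy per surface area is COM × distance / CCS, normalized at
100 kDa. Under these assumptions it falls steeply with mass — the
quantitative face of the stability plateau megadalton ions enjoy.

The exact radius/pressure combination behind any particular printed
collision count is an instrument condition, not a package constant; the
operations take them as parameters, and the presets (gauge read-outs
2.6e-10 and 8e-10 mbar, nitrogen or xenon) give order-of-magnitude
realistic counts (tens to low hundreds per 4 s transient).

## Numerical and scale choices

Analyses in this vignette's scale were chosen for a single desk CPU: the
default 250 kHz sampling covers all axial frequencies at m/z > ~4,350 and
keeps a 4 s transient at one million samples (the 4 MHz full instrument
rate is configurable but not needed, as no physics above 125 kHz is
simulated). Unit tests use a 131,072 Hz variant with ions above m/z
21,000. The test-suite ensembles (up to 500 ions per duration, 100
noise-only transients per duration, 1,000-ion loss tables) are sized so
the whole suite completes in minutes while leaving the Monte-Carlo error
well inside each asserted tolerance. Samples are stored as 32-bit floats
(detector dynamic range does not warrant more); all spectral accumulation
is double precision.

Degenerate inputs are handled explicitly rather than by accident: empty
ion lists simulate pure noise; vacuum (zero density) reports zero
collisions with an infinite mean free path and a flag; noiseless charge
ensembles are flagged degenerate instead of power-law fitted; FWHM
measurement flags unresolved peaks; half-height ties are resolved by
linear interpolation toward the first crossing.

## Known limitations

* Magnitude-mode segment spectra limit centroid precision; the absorption
  surrogate needs the true initial phase and is therefore simulation-only.
* The greedy tracer is not a global assignment: genuinely crossing ions
  are excluded upstream by the isolation filter, not resolved.
* The doublet pairing gate can join unrelated ions that hand over within a
  few segments (loose integer tolerance by design; see above).
* Drift correction assumes the per-window drift stays below the segment
  bin; ions losing mass fast enough to split even segment spectra are lost
  to both paths.
* All quantitative claims are about this synthetic model of the
  instrument; electronic ringing, harmonics and space-charge effects on
  real transients are out of scope.
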