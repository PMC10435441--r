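---
title: "Methods: optical modelling and detection of sweat-film formation in wrist PPG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optical modelling and detection of sweat-film formation in wrist PPG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ppgsweat)
```

# The problem

When a wrist-worn optical sensor sits on skin during exercise, a thin film of
sweat forms between the device and the skin. The film changes what the
photodetectors see, most strongly in the near infrared: 1450 nm sits on a
water absorption band (pure water absorbs roughly 60 times more strongly
there than at 970 nm), so a growing film attenuates the 1450 nm return while
the 970 nm channel responds far more weakly. `ppgsweat` models this end to
end: the photon transport that explains *why* the channels move, a synthetic
recording generator that emulates the kind of treadmill-run data such a
sensor produces, and the analysis chain (windowed features, paired-window
classifiers, trend-slope onset detection) that turns multi-wavelength PPG
into a sweat-onset call.

# The optical skin model

Skin is represented as a planar stack: an optional topical water film, seven
functional sub-layers (stratum corneum, living epidermis, papillary dermis,
upper blood-net dermis, reticular dermis, deep blood-net dermis, hypodermis)
and a semi-infinite base continuing the hypodermis. Each layer carries
spectrally resolved absorption $\mu_a(\lambda)$, scattering
$\mu_s(\lambda)$, anisotropy $g$ and refractive index $n$.

Absorption follows a linear volume-fraction mixing rule,

$$\mu_a = C_{mel}\,\mu_{a,mel} + C_{blood}\bigl(S\,\mu_{a,HbO_2} +
(1-S)\,\mu_{a,Hb}\bigr) + f_w\,\mu_{a,water} + \mu_{a,base},$$

with melanin hosted in the living epidermis and per-layer blood and water
fractions. The chromophore spectra are shipped as package-authored
literature-class tables: a Hale--Querry/Segelstein-class water spectrum with
local maxima at the 975 and 1448 nm bands, Prahl-class hemoglobin extinction
anchors (converted to whole-blood absorption at 150 g/L hemoglobin), a
power-law melanosome model ($\propto \lambda^{-3.33}$) and the standard skin
baseline formula. These are approximations with the correct band structure
and magnitudes, not digitizations of any measured figure; the water-band
contrast that the method rests on ($\mu_a(1450)/\mu_a(970) \gg 1$) is tested
explicitly. Reduced scattering uses $\mu_s'(\lambda) = a(\lambda/500)^{-b}$
per tissue class with $\mu_s = \mu_s'/(1-g)$. Refractive indices (film 1.33,
skin 1.34--1.50, ambient 1.0) are standard tissue-optics values; the source
study never states them. All layer parameters are overridable, so
ultrasound-measured thicknesses can be injected verbatim.

# The Monte Carlo transport

`run_mc()` traces photon packets through the stack: exponential free paths,
Henyey--Greenstein deflection sampling, unpolarized Fresnel
reflection/refraction at every index mismatch (including entry), and
detection at the top surface.

Two numerical choices deserve justification:

* **Continuous absorption weighting.** The interaction coefficient used for
  path sampling is $\mu_s$ alone; absorption never terminates a packet but
  decays its weight as $W \leftarrow W e^{-\mu_a l}$ along every segment,
  with the difference credited to the absorbed tally. Sampling paths with
  $\mu_a + \mu_s$ *and* separately decaying the weight by $e^{-\mu_a l}$ --
  a literal reading of the usual shorthand description -- would double-count
  absorption and break the scattering-free Beer--Lambert limit
  ($T = e^{-\mu_a d}$), which the tests verify exactly. The variant used
  here is the standard unbiased one; it reproduces the van de Hulst
  semi-infinite benchmark (albedo 0.9, isotropic, matched boundary:
  $R = 0.4174$) within Monte Carlo error, cross-checked against an
  independently coded MCML-style oracle that consumes sampled optical depth
  across boundaries.
* **Russian roulette at a very low threshold.** The classical threshold of
  $10^{-4}$ is far too high for this sensor: at 1450 nm dermal
  $\mu_a \approx 2\,\mathrm{mm^{-1}}$, and packets reaching the detector
  carry weights of order $10^{-7}$--$10^{-9}$. Because the walk itself is
  absorption-independent under continuous weighting, letting packets run to
  weight $10^{-12}$ (the default; survival factor 0.1, survivors rescaled
  unbiasedly) costs little and keeps the 1450 nm estimates usable. The
  weight ledger (detected + escaped + transmitted + absorbed + truncated =
  launched) balances to $10^{-6}$ relative with roulette active because
  survivor rescaling is booked as a negative absorption credit.

Geometry follows the hardware: a pencil beam entering at a configurable
incidence angle, a 1.5 mm square detector centered 3.5 mm (or 5.5 mm) away,
and an optional numerical-aperture cut (default none -- the study names the
NA as a design parameter without a value). Packets exceeding the interaction
cap go to a dedicated truncation tally, tested to stay below 0.1%.

**Aperture versus surface detection.** At 970 nm and in the visible, the
aperture-detected estimate behaves well. At 1450 nm no desk-scale photon
count makes the 3.5 mm aperture estimate statistically useful (weights
$\sim e^{-20}$); the film/angle sweeps therefore default to the total
top-surface reflectance for trend work (`detect = "total"`). The film
downtrend at 1450 nm is a round-trip attenuation effect common to every exit
position, so the surface-integrated quantity tests the same physics at
usable variance. One honest side effect: in *surface-integrated* terms the
970 nm film response in this model is a mild *downtrend* (the film
index-matches the air--skin interface, reducing the specular component that
the surface integral includes). This is consistent with the source study's
own caveat that the 970 nm uptrend holds "generally (but not always)", and
is why only the 1450 nm direction is asserted anywhere in the tests; the
970 nm trend is reported informationally.

# The synthetic recording generator

No clinical recordings are available, so `generate_run()` produces the
stated world the analysis is tested against: 25 Hz recordings of four PPG
channels (535/940/970/1450 nm; 645 available as an alias for the hardware
description's naming) plus 3-axis accelerometer and gyroscope, default 22
minutes. Each PPG channel is

baseline × (1 + film drift) + cardiac pulse train + motion artifact + noise,

with: heart rate relaxing from 75 to 155 bpm with a 3-minute time constant
(plus mild sinus variation); a cardiac waveform of three harmonics at fixed
relative amplitudes (1, 0.4, 0.15) and AC/DC ratio 1.5%, typical of wrist
PPG; motion components at the step frequency (170 spm → 2.83 Hz) and arm
swing (1.4 Hz), amplitude-coupled into the IMU channels; white plus slow
pink-like noise at 0.2% of baseline each; and a film trajectory that is zero
until onset $t_0$ (default 600 s) and then rises as a saturating ramp with a
5-minute time constant to 300 µm -- sweat films do not appear instantly.
The film maps to per-channel baseline drift through trend curves whose
default parametric forms mirror the simulated directionality (up at 970 nm,
down 15% saturating at 1450 nm); curves fitted from `film_angle_map()`
output can be substituted.

What the generator does *not* emulate: real pulse morphology and its
beat-to-beat variability, baseline wander from strap pressure, ambient-light
transients, subject-to-subject anatomy, and the uncertain real mapping from
film thickness to detected counts. A green test on this world therefore
establishes that the *pipeline* recovers what the stated world contains --
not that the hardware would achieve the same numbers on human subjects.

# Features

Windows are 3.5 min (210 s), stepped by 20 s. Eleven time-domain statistics
(mean, median, max, min, unbiased std and variance, skewness, excess
kurtosis, IQR, unscaled median absolute deviation, least-squares trend slope
per second) are computed on the raw signal; the same eleven are applied to
each channel of a generalized Morse wavelet magnitude spectrum
($\gamma = 3$, $\beta = 20$, the typical analytic-wavelet setting; 26
log-spaced channels covering 0.1--12.5 Hz, i.e. up to the 25 Hz Nyquist).
Channel center frequencies are exposed in Hz, so the pulse band is
addressable physically rather than by an index that depends on a scale
convention. Names follow `<wavelength>_<domain>_<function>[_<channel>]`
(e.g. `970_td_skew`, `1450_fd_median_7`) and round-trip through a parser.
Degenerate constant windows get skewness/kurtosis of 0 with a logged
warning, keeping vectors finite. The source study's total of 642 features
does not decompose uniquely into wavelengths × channels × statistics, so
the count here is configuration-driven: with the default two NIR wavelengths
and 26 channels, $11 \cdot 2 \cdot (1 + 26) = 594$ features.

# Paired-window classification

Each run contributes one negative (run-start window) and one positive
(run-end window) feature vector. The sweep starts with the windows at the
run's ends and moves both toward each other by 10 s per 20 s step (so the
center-to-center gap shrinks by 20 s), stopping before they overlap; a
22-minute run gives 46 classifiers. The number of sweep steps is a
consequence of run duration -- the study's count of 23 reflects its own
(unpublished, per-subject) durations and is reproduced only by rule, not as
a constant.

No gradient-boosting library is available in this environment, so the
learner is implemented in the package: logistic-loss gradient boosting with
Newton leaf values, depth-2 trees, learning rate 0.01 -- the two published
hyperparameters -- and this package's own defaults for the rest: 100
rounds (the common library default) and a minimum of 5 observations per
leaf. The usual library default of 20 per leaf would forbid *any* split at
the 36 training rows of the scaled-down 24-run acceptance world, which is a
property of the library's tuning for large data, not of the method. Fitting
is fully deterministic (no subsampling; ties broken by feature index);
cross-validation is grouped at the run level with a seeded round-robin deal,
so no run ever appears on both sides of a fold. Feature importance is an
exact path-dependent Shapley attribution: per tree, subsets of the (at most
three) used features are enumerated and absent features marginalized by
training-cover fractions -- mathematically the TreeSHAP quantity, affordable
because depth-2 trees are tiny. Attributions satisfy local accuracy
(they sum to the margin), which is tested.

# Onset detection

The 1450 nm channel is smoothed by a centered moving average over a 180 s
window (inside the study's 2--5 min optimum), a rolling least-squares slope
over the same window produces units/minute, and the slope series is
normalized by its per-run median absolute deviation -- making the detector
invariant to affine rescaling of raw counts. Onset is the first time the
normalized slope holds the expected sign beyond a threshold of 2
robust-scale units for a sustained 60 s. The study gives the trend
association but no numeric rule; these values are declared here, once:
threshold 2 for a ~2% two-sided false-trigger rate under the smoothed
noise's autocorrelation (tested empirically on flat signals at threshold 3
per the stricter example), sustain 60 s to reject transient excursions
shorter than a third of the smoothing window. The expected direction is a
parameter because the study's own sign conventions differ between its
reflectance simulations (downtrend with film) and its cohort trend figure
(positive-then-negative slope sequence); the detector takes the caller's
convention rather than pretending to reconcile them. Cohort aggregation
bins normalized slopes into 5-minute windows averaged over groups of 5
subjects, reproducing the study's summary surface layout.

# Sensor fusion

Motion frequencies are estimated from the Hann-windowed periodogram of the
combined detrended IMU magnitude: peaks above 30× the median power (a
floor chosen so white-noise maxima, which reach ~15× the median at these
lengths, do not trigger) become artifact bands of ±0.15 Hz, with first
harmonics added. Suppression zeroes those Fourier components of the PPG
before feature extraction. If the pulse band is entirely covered, or no
credible cardiac line survives outside the bands (the surviving pulse-band
maximum falls below 20% of the in-band maximum -- motion sitting exactly on
the cardiac frequency), the channel is flagged unusable instead of being
silently cleaned. Suppression can only remove energy, never add it.

# Numerical and testing notes

* All randomness flows from one master seed through deterministic substream
  derivation (`seed` stays below $2^{31}$); the Monte Carlo uses per-packet
  xoshiro256++ substreams, so results are independent of R's RNG state.
* Monte Carlo assertions are made at 3 combined standard errors; trend
  labels use a 3-sigma slope test against propagated per-cell errors.
* Acceptance-scale checks run at the stated desk scale (24 runs for the
  classifier sweep, 50 for onset recovery, $10^5$ packets per Monte Carlo
  point); unit tests use smaller worlds for speed.
* Known limitations: planar layers only (no curvature or voxel anatomy), no
  polarization or fluorescence, flat spectral anisotropy per layer, no
  subject-level physiology in the generator, and chromophore tables that are
  class-level approximations rather than measured spectra.
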