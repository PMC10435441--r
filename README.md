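# ppgsweat

Optical modelling and machine-learning detection of sweat-film formation in
wrist photoplethysmography (PPG).

During exercise, a thin film of sweat forms between a smartwatch and the
skin. Because 1450 nm sits on a strong water absorption band
(μ<sub>a,water</sub>(1450) ≫ μ<sub>a,water</sub>(970)), a growing film pulls
the 1450 nm reflectance down while the 970 nm channel barely responds — a
spectral signature that makes the *onset of sweating* optically detectable.
`ppgsweat` is for sensor designers and biosignal researchers who want to
study this mechanism end to end without hardware:

* **Photon-packet Monte Carlo** through a seven-layer optical skin model
  (melanin, oxy/deoxy-hemoglobin, water, baseline chromophores; per-layer
  scattering power laws) plus a topical water film, with Henyey–Greenstein
  scattering, Fresnel boundaries, unbiased Russian roulette and a square
  detector at the hardware's 3.5/5.5 mm LED–PD separations. Core loop in
  C++ (Rcpp).
* **Sensor sweeps**: reflectance spectra, film-thickness × incidence-angle
  maps, and error-aware trend labelling.
* **Synthetic run recordings** with ground truth: four PPG channels
  (535/940/970/1450 nm) + 6-axis IMU at 25 Hz, heart-rate drift, step and
  arm-swing artifacts, and a film-drift trend starting at a known onset
  time.
* **Analysis pipeline**: 11 windowed time-domain statistics + generalized
  Morse wavelet features; paired-window (run-start vs run-end)
  gradient-boosted tree classifiers (depth 2, learning rate 0.01) with
  grouped cross-validation and exact Shapley feature ranking; IMU-informed
  artifact suppression; and a 1450 nm trend-slope onset detector.

The statistic at the core of the detector: smooth the channel over a
2–5 min window, take the rolling least-squares slope s(t) (units/min),
normalize by its per-run robust scale, and call onset at the first time

  sign(ŝ(t)) = expected direction and |ŝ(t)| ≥ 2 sustained for 60 s,

where ŝ = s / MAD(s).

## Worked example

```r
library(ppgsweat)

# --- physics: what does a 300 um sweat film do at 1450 nm?
grid <- wavelength_grid(c(970, 1450))
cfg  <- sim_config(n_photons = 5e4, seed = 7)
run_mc(build_skin_stack(grid = grid),                         geometry = sensor_geometry(), config = cfg, wavelength = 1450)
run_mc(build_skin_stack(grid = grid, film_thickness_mm = 0.3), geometry = sensor_geometry(), config = cfg, wavelength = 1450)
```

```
<detection_record> 1450 nm, 50000 packets (seed 7)
  detected reflectance: 8.694e-07 +/- 3e-07 (229 packets)
  total top reflectance: 0.0839 +/- 0.0011
<detection_record> 1450 nm, 50000 packets (seed 7)
  detected reflectance: 1.07e-07 +/- 4.1e-08 (233 packets)
  total top reflectance: 0.02627 +/- 0.00063
```

The film cuts the 1450 nm surface reflectance from 8.4% to 2.6% — the
downtrend the detector exploits. (At 1450 nm the aperture-detected estimate
is tiny and noisy by physics; see the methods vignette for why trend work
uses the surface-integrated value.)

```r
# --- signal: generate a 22-min run with film onset at t0 = 600 s and detect it
rec <- generate_run(run_profile(), seed = 42)
tr  <- trend_series(ppg_channel(rec, "1450"), rec$fs, smooth_s = 180)
detect_onset(tr, direction = -1)
```

```
<onset_call> onset at 556 s (direction -1, confidence 1.00)
```

The call lands 44 s before the true onset (the centered smoothing window
responds as drift enters its leading edge) — well inside the 2-minute
accuracy target.

```r
# --- full synthetic pipeline (gen-data -> features -> train -> onset)
run_pipeline(list(seed = 5, out_dir = "out",
                  gen_data = list(n_runs = 8, duration_s = 600)))
```

A command-line interface with the same stages is installed at
`inst/cli/ppgsweat` (`simulate`, `map`, `gen-data`, `extract-features`,
`train-windows`, `detect-onset`, `run-all`), configured by YAML or JSON.

## Layout

`R/` exported model + pipeline; `src/` Monte Carlo tracer and boosted-tree
learner (Rcpp); `inst/extdata/` chromophore tables (package-authored
literature-class approximations, see headers); `vignettes/` the methods
vignette; `tests/testthat/` unit, property and acceptance suites including
an independently coded Monte Carlo oracle.
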