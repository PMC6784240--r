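# dopplertrace

Automated extraction of **peak blood-velocity profiles** (Doppler-shift
envelopes) from pulsed-Doppler echocardiography spectrogram images.

Clinicians and hemodynamics researchers routinely read peak velocities —
mitral-inflow E and A waves, outflow envelopes, cardiac time intervals — off
spectral Doppler displays by hand, a tedious and subjective process. Traced
envelopes are also the natural boundary conditions for computational
hemodynamic models. `dopplertrace` replaces the manual tracing with two
simple, deterministic per-column thresholding searches, plus the supporting
analytics needed to check and use the result.

## The method

A spectrogram is an 8-bit grayscale matrix `μ(X, Y)` in `[0, 255]`: columns
`X` are time, rows `Y` the velocity axis, with a zero-velocity baseline row
`Y_base` inside a region of interest (ROI) bounded by rows `n_up` (top) and
`n_lo` (bottom). Per column, with `μ_max,X` the maximum intensity of the
column within the ROI:

- **Method 1 (border-inward; lower limit).** The upper/lower edges are the
  smallest/largest `Y` with `μ(X, Y) > θ₁ · μ_max,X`. The search effectively
  starts at the ROI borders and moves toward the baseline, so it uses a
  relatively large threshold (reference `θ₁ = 0.3`) to resist border
  artifacts, and it *underestimates* the velocity magnitude.
- **Method 2 (baseline-outward; upper limit).** The reference maximum is
  taken over a small window of `a` rows next to the baseline; starting from
  that maximum the search walks away from the baseline and stops at the
  first row with `μ(X, Y) < θ₂ ·` (window max); the edge is the last
  supra-threshold row. A small threshold (reference `θ₂ = 0.05`) makes this
  an *overestimate*.
- **Combined profile.** `P_avg = (P₁ + P₂) / 2`, column-wise, for the upper
  and lower traces separately.

Both searches threshold *relative to the per-column maximum*, so they are
invariant to column brightness scaling, and by construction they return
exactly one upper and one lower edge per column — a gradient detector such
as Canny may return fewer or more (artifacts), which is the package's
built-in comparison baseline.

Around the core: optional moving-average smoothing over a
`(2p+1) × (2q+1)` window (reference `p = q = 3`) that removes speckle
outliers before extraction; axis calibration (cm/s per row, ms per column)
to convert edge rows to signed velocities; E/A wave measurement;
Bland–Altman agreement (`bias ± 1.96 SD`) between the two methods; and
profile magnitude spectra. A synthetic spectrogram generator with exact
ground-truth envelopes makes every stage testable without clinical images.

## Worked example

```r
library(dopplertrace)

# a synthetic mitral-inflow recording: 3 beats, E/A lobes 67/72 cm/s,
# 0.34 cm/s per row and 1.9 ms per column
g <- generate_spectrogram(synth_spec(seed = 42))
g$image
#> <gray_image> 456 rows (velocity axis) x 1280 columns (time), intensities 0.0..215.7

smoothed <- smooth_image(g$image, smoothing_params(3, 3))
e1 <- detect_edges_method1(smoothed, g$roi, theta1 = 0.3)
e2 <- detect_edges_method2(smoothed, g$roi, theta2 = 0.05)
e1
#> <edge_profile> method 'method1', 1280 columns (0 missing upper, 0 missing lower)

combined <- average_profiles(e1, e2)
v <- rows_to_velocity(combined, g$roi, axis_calibration())
v$positive
#> <velocity_profile> 1280 samples at dt = 0.0019 s, range 2.0..70.2 cm/s

measure_waves(v$positive)
#> <wave_measurements> 3 beat(s): E = 65.22 cm/s, A = 70.10 cm/s

v1 <- rows_to_velocity(e1, g$roi); v2 <- rows_to_velocity(e2, g$roi)
bland_altman(v1$positive$velocity, v2$positive$velocity)
#> <agreement_stats> n = 1280, bias -2.061, SD 1.965, LoA [-5.913, 1.791]
```

The three detected beats recover the generator's E (67) and A (72 cm/s)
lobes to within a couple of cm/s — the residual comes from the intensity
decay band at the spectral edge, which biases the lower-limit method
slightly inward. The negative Bland–Altman bias says method 1 sits below
method 2, i.e. the two thresholds bracket the true envelope from below and
above.

For clinical frames, write a YAML config (`n_up`, `n_lo`, `y_base`,
`theta1`, `theta2`, calibrations; see `?read_config`) and either call
`run_pipeline(config, frames, out_dir)` or use the thin CLI in
`inst/cli/dopplertrace` (`extract`, `synth`, `evaluate`,
`suggest-thresholds` subcommands). `suggest_thresholds()` locates the two
ROI histogram modes (background 0, foreground ≈ 175) and reports the
candidate threshold range between them; final thresholds remain the user's
clinical judgement.

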