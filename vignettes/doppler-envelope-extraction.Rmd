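---
title: "Extracting peak velocity profiles from Doppler spectrograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting peak velocity profiles from Doppler spectrograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dopplertrace)
```

## The problem and the model

A pulsed-Doppler spectrogram displays blood speed against time: each pixel
column is an instant, each row a velocity, and brightness encodes the
returned Doppler power at that velocity. Flow toward the transducer is
drawn above a zero-velocity baseline row, flow away below it. The *peak
velocity profile* (envelope) is the outer edge of the bright region in each
column — the fastest blood at that instant — and is what clinicians read
off manually when they measure mitral E/A waves or outflow time intervals.

`dopplertrace` treats a frame as a scalar intensity field
$\mu(X, Y) \in [0, 255]$ on a pixel grid (columns $X$ = time, rows $Y$ =
velocity axis, rows increasing downward as displayed; all indices are
1-based, matching both R and the pseudo-code convention for this family of
algorithms). The user supplies a region of interest: top and bottom rows
$n_{up} < n_{lo}$ bracketing the spectrogram band, and the baseline row
$Y_{base}$ between them, read off the machine display. Within the ROI, the
per-column maximum $\mu_{max,X}$ serves as the reference intensity, which
makes everything that follows invariant to per-column brightness scaling
(gain drift, depth-dependent attenuation).

Two complementary edge searches are run per column:

**Method 1 — border-inward, lower limit.** The upper edge is the smallest
$Y$ in the ROI with $\mu(X,Y) > \theta_1\,\mu_{max,X}$ and the lower edge
the largest such $Y$. Conceptually the scan starts at the ROI borders,
where machine annotations (text, scale marks) may lurk, so a relatively
large threshold ($\theta_1 = 0.3$ by default) is needed — and the first
supra-threshold pixel it meets inside the intensity falloff of the
spectral edge is already inside the true envelope: the method
underestimates the velocity magnitude.

**Method 2 — baseline-outward, upper limit.** The reference maximum is
anchored near zero velocity: $\mu_{max,X,up} = \max \mu(X, Y_{base}-a
\ldots Y_{base})$ over a search window of $a$ rows. From the row attaining
it, the search walks away from the baseline and stops at the first row
with $\mu < \theta_2\,\mu_{max,X,up}$; the edge is the last
supra-threshold row before the stop (if the threshold is never crossed the
edge is the ROI border itself). Walking outward from strong signal, a
small threshold ($\theta_2 = 0.05$) is appropriate, and the method
overestimates the magnitude. The lower half mirrors this below the
baseline.

The combined estimate averages the two column-wise,
$P_{avg} = (P_1 + P_2)/2$, separately for the upper and lower traces; the
under- and over-estimates bracket the envelope, so their mean is a
smoother compromise.

Assumptions worth stating: a single un-aliased envelope per half-column
(no wrap-around), a dark background with bright foreground (the ROI
histogram is bimodal, background mode at 0 and foreground near 175 on the
modelled display), and a user-supplied baseline (the colored baseline
overlay is not auto-detected).

## Parameters

| parameter | units | default | role |
|---|---|---|---|
| `theta1` | fraction of column max | 0.3 | method-1 threshold; higher resists border artifacts, lower hugs the envelope |
| `theta2` | fraction of window max | 0.05 | method-2 threshold; small because the walk leaves the signal from inside |
| `search_window` (`a`) | rows | 10% of the smaller ROI half-height | anchors method 2's reference maximum near zero velocity |
| `p`, `q` | columns, rows | 3, 3 | smoothing half-extents: a 7×7 moving-average window |
| `velocity_per_pixel` | cm/s per row | 0.34 | vertical calibration of the display |
| `time_per_pixel` | ms per column | 1.9 | horizontal calibration; implies fs = 1000/1.9 ≈ 526.3 Hz |

No reference value exists for the search window `a`; its purpose is only
to anchor the reference maximum to near-baseline signal, so a small
fraction (10%) of the half-height is used and it is configurable. The
displayed sampling rate of such recordings is sometimes quoted as 532 Hz
alongside a 1.9 ms pixel pitch; these are mutually inconsistent (1/1.9 ms
= 526.3 Hz), and the package always derives the sampling frequency from
`time_per_pixel` rather than hard-coding a rate.

Thresholds on clinical images are a clinical judgement — they are chosen
so the traced profile satisfies an expert eye. `suggest_thresholds()`
locates the two ROI histogram modes and reports the intensity fractions
between them as the candidate range, but never picks for the user.

## Numerical choices

- **Inclusive ROI bounds.** Rows `n_up..n_lo` are included in every scan;
  closed bounds are the safer superset where prose and pseudo-code
  disagree on strictness.
- **Strict inequalities.** Method 1 keeps `μ > θ₁·μmax`; method 2 stops on
  `μ < θ₂·μmax` (equivalently, continues while `μ ≥ θ₂·μmax`), exactly as
  the criteria are stated.
- **Ties for a maximum** resolve to the first (smallest-row) occurrence —
  deterministic and matching a top-to-bottom scan.
- **Method-2 stopping rule.** The printed per-column recipe for the second
  criterion contains an internally inconsistent row-range expression; the
  implementation follows the prose intent: walk from the window-maximum
  row toward the ROI border and return the last supra-threshold row before
  the first sub-threshold one. This is what makes the method an upper
  limit.
- **Missing columns.** A column (or half-column) whose reference maximum
  is 0 carries no signal; it yields an `NA` edge, never an error, and
  converts to 0 cm/s with a `missing` flag — the physiological null.
- **Smoothing borders.** The moving-average window shrinks to its
  intersection with the image near borders (mean over available pixels):
  no pixel values are invented and constant images are reproduced exactly.
  Smoothing is applied to the cropped ROI so display annotations outside
  the ROI cannot bleed in. Implementation is via integral images, O(1) per
  pixel in the window size.
- **Annotation masking.** Bright text inside the ROI corner derails the
  border-inward search. An optional user-supplied mask zeroes those
  pixels before extraction; auto-detection of overlays is out of scope.
- **Spectra.** `profile_spectrum()` removes the mean before the DFT (the
  DC term would otherwise mask the fluctuation content of interest) and
  reports the one-sided unnormalised magnitude up to Nyquist.
- **E/A measurement.** No standard procedure exists at the level of "find
  E and A": the package detects local maxima of the positive trace with a
  configurable prominence floor (default 10 cm/s) and minimum separation
  (0.15 s), groups peaks into beats wherever the inter-peak gap exceeds
  0.4 s (an E–A interval is a few tenths of a second; successive beats are
  a systole apart), and labels the earlier peak of each beat E, the later
  A. This is an interpretation — flagged as such — chosen to be the
  minimal standard peak-picking consistent with mitral-inflow physiology.
- **Bland–Altman** uses per-column differences between the two methods'
  calibrated profiles and the sample (n−1) standard deviation, the
  standard practice.

## The synthetic generator

Every stage is testable without clinical data through
`generate_spectrogram()`, which emulates an ROI-scale mitral-inflow
recording and returns the exact ground-truth envelope alongside the image.
The defaults are the package's fixed study conditions: 456 rows with the
baseline at row 216 (so ~215 rows ≈ 73 cm/s of headroom above the
baseline at 0.34 cm/s per pixel), ~0.8 s beats (421 columns at 1.9 ms),
raised-cosine E and A inflow lobes of 67 and 72 cm/s, one 60 cm/s systolic
outflow lobe below the baseline, foreground intensity 175 on black.

Four features of real displays are modelled deliberately:

1. **Spectral-edge decay.** Intensity ramps from foreground to zero over
   the outer 15% of each filled half-column (spectral broadening). This
   band is what makes the two thresholds genuinely under/over-estimate;
   with a hard edge both methods coincide and the two-limit structure
   vanishes.
2. **Wall-clutter band.** Four rows on each side of the baseline always
   carry foreground signal, as the wall filter leaves on a real machine.
   Without it, columns between lobes would hold a single signal pixel, and
   after smoothing method 2's anchor maximum would dilute below the noise
   floor and the walk would run away to the border.
3. **Speckle grains.** Sparse bright single-pixel grains (density
   1.5·10⁻⁴ per pixel, near-foreground intensity). Grains in the
   background are what capture the border-inward method-1 scan and produce
   the outlier columns and sudden velocity jumps seen in raw extracted
   profiles. Zero-mean Gaussian noise alone cannot produce them: both
   searches threshold against per-column maxima and are nearly immune to
   it.
4. **Additive Gaussian noise** (sd 10, clipped to [0, 255]) for the
   overall texture; it keeps the ROI histogram bimodal while leaving the
   clipped background floor (≈4) safely below method 2's stopping
   threshold (≈8.75).

An optional bright "text" block in the upper-left corner reproduces the
annotation-overlay failure mode for masking tests.

Under these conditions the qualitative behaviour of the method on real
images is reproduced and is asserted by the test suite: raw method-1
profiles carry speckle-driven outliers (≈4.5 rows mean absolute edge
error) that 7×7 smoothing removes (≈2.5 rows), method 2 is nearly exact
raw and is dilated outward by smoothing, the Bland–Altman SD between the
methods shrinks with smoothing while the |bias| — the separation between
the lower and upper limits — grows, and high-frequency profile power
drops. The artifact-reduction property is asserted for method 1
specifically: smoothing is a rescue for the artifact-prone border-inward
search, whereas the baseline-outward walk has nothing to rescue and any
blur can only move its near-exact edge outward.

What the generator does *not* emulate: physically realistic correlated
ultrasound speckle statistics, aliasing/wrap-around, beat-to-beat
variability, ECG traces and measurement overlays, or color-Doppler maps.
Passing tests on synthetic data therefore demonstrate algorithmic
correctness and the direction of the smoothing/agreement effects, not
clinical accuracy on any particular machine.

## Scale of the shipped checks

The test-suite and acceptance-script problem sizes are chosen to exercise
every property at comfortable desk scale: oracle equivalence on one
hundred 64×64 random images, edge-count guarantees on twenty 456×320
frames across noise levels 0–25, smoothing/agreement statistics on twenty
456×640 two-beat replicates, and full-size (456×1280, three-beat) frames
for recovery and E/A checks. All randomness is seed-derived and
deterministic.

## Known limitations

- One envelope per half-column: aliased (wrapped) Doppler traces are out
  of scope.
- The baseline row and ROI must be supplied; they are not auto-detected.
- Frames are processed independently; no stitching of a sweeping display
  across frames.
- E/A labelling assumes two-peak diastolic inflow; fused E/A peaks at high
  heart rates will be reported as a single E.
- The Canny-style baseline in `canny_edge_map()` is a compact detector
  built from derivative-of-Gaussian gradients, non-maximum suppression and
  hysteresis; it is intended for qualitative artifact comparison
  (`edges_per_column()`), not as a reference implementation of any
  particular library's Canny.
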