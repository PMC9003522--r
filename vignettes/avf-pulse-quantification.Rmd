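---
title: "Quantifying arteriovenous fistula pulse waves from non-contact video"
author: "avfpulse"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Hemodialysis patients carry a surgically created arteriovenous fistula
(AVF): an anastomosis between the radial artery and the flexor cutaneous
vein that supplies the high blood flow dialysis needs. The fistula's
condition is routinely assessed by auscultation and palpation, which are
qualitative, operator-dependent, and require skin contact. A camera looking
at the fistula offers a non-contact alternative: each video pixel carries a
periodic luminance variation driven by the cardiac cycle, because the
distending vessel moves its parietal surface toward the camera (more
reflected light) and simultaneously casts a larger lateral shadow (less
light beside the vessel). The observed per-pixel waveform decomposes into a
heartbeat component and a thrill component, the palpable 5&ndash;10&nbsp;Hz
vibration caused by turbulent flow at the anastomosis:

$$W_{\mathrm{AVF}}(t) = W_{\mathrm{heartbeat}}(t) + W_{\mathrm{thrill}}(t).$$

This package implements the full analysis chain for such recordings:
channel extraction, spatial moving-average denoising with kernel-size
optimization, the SNAVF quantification statistic, color-mapped
visualization, and cohort-level summaries. Because clinical recordings
cannot be redistributed, the package ships a synthetic video phantom that
embodies the same signal structure and drives every test.

## Why luminance

Pulse visibility can be compared across luminance, hue and saturation
channels by the peak-to-peak value of the extracted waveform
(`peak_to_peak()`); luminance wins by a wide margin, so the quantification
pipeline runs on luminance. The camera's "luminance" is not formally
defined by the acquisition hardware, so the package uses the fixed,
documented ITU-style weighted sum $0.299R + 0.587G + 0.114B$
(`to_channel(..., "luminance")`). The weights are configurable; with a blue
illuminator one may prefer the raw blue channel
(`luma_weights = c(0, 0, 1)`). Hue and saturation use the standard hexcone
model; hue of achromatic pixels is undefined and is set to 0 with an
`"achromatic"` flag attribute so no NaN ever reaches the FFT stage.

## Spatial moving-average filtering

Every pixel observes the same in-phase pulse while sensor noise is
independent across pixels, so averaging an $N \times M$ neighborhood acts
like additive averaging of $N M$ repeated measurements: the pulse survives
and the i.i.d. noise variance falls as $1/(N M)$ (verified as a test
property). `moving_average()` convolves each frame with a centered kernel
of weights summing to one, sliding one pixel at a time. Two numerical
choices matter:

* **Boundary handling.** Only fully interior pixels are produced ("valid"
  convention); the output frame shrinks by $N-1$ rows and $M-1$ columns and
  `origin_offset` records where it sits in source coordinates. The region
  of interest sits near the anastomosis, well away from frame edges, and
  padding would bias band powers at boundaries. A reflect-padding mode
  exists but is off by default.
* **Coordinates.** All indices are 1-based `(row, col)` with the origin at
  the top-left pixel of frame 1, following R convention throughout.

The standard sweep covers square kernels of 1 to 201 pixels in steps of 2
(`kernel_sweep_sizes()`, 101 sizes); at the assumed pixel pitch of 0.08
units per pixel the largest kernel spans `kernel_extent(201)` = 16.08
units. Odd sizes guarantee a center pixel, which keeps the filtered trace
co-located with the ROI across the whole sweep. The fast implementation
uses per-frame integral images; equality with a literal double-loop
convolution to $10^{-9}$ is part of the test suite.

## The SNAVF statistic

Each candidate trace (the kernel-averaged pixel at the ROI) is analyzed on
its first 256 samples with a rectangular-window FFT; at 40 fps the bin
spacing is 0.15625 Hz. Band-pass filters are realized as FFT masks with
inclusive edges (`band_pass()`). The signal band is 1&ndash;5 Hz (resting
heart rates of 60&ndash;100 bpm and the second harmonic); the noise band is
10&ndash;19 Hz, above the 5&ndash;10 Hz thrill band and below the 20 Hz
Nyquist limit. Then

* `signal_power()` (AVFs) = power of the largest bin in 1&ndash;5 Hz (the
  fundamental) plus the largest bin within one bin of twice that frequency
  (the second harmonic). The harmonic is counted even when $2 f_0$ exceeds
  5 Hz, because the signal is defined as fundamental-plus-harmonic, not as
  all in-band energy.
* `noise_power()` (AVFn) = sum of the two largest bin powers in
  10&ndash;19 Hz.
* `snavf_sweep()` computes the ratio for every kernel size and reports
  $\mathrm{SN}_{\mathrm{AVF}} = \max_N \mathrm{AVFs}/\mathrm{AVFn}$ together
  with the optimal $N$.

Numerical conventions: bin power is the squared magnitude of the
unnormalized DFT (any fixed normalization cancels in the ratio; the
convention is documented so absolute powers are reproducible and satisfy
Parseval's identity $\sum_k |X_k|^2 = 256\sum_t x_t^2$). The segment mean
is removed before transforming, since the baseline luminance would dwarf
band powers. The window is rectangular by default — it keeps on-grid tones
exact, which the test oracles rely on; a Hann option exists for off-grid
field data. Ties in the ratio (within a relative $10^{-9}$) go to the
smallest kernel, the cheapest filter. An exactly zero AVFn (possible only
for degenerate synthetic input) yields an `Inf` sentinel with a warning
rather than an error.

Why the ratio rises and then falls with $N$: while the kernel fits inside
the in-phase vessel region the signal amplitude is unchanged and the noise
power drops as $1/N^2$, so the ratio grows roughly as $N^2$. Once the
kernel swallows the anti-phase lateral shadow, the averaged pulse amplitude
shrinks and the ratio declines. The optimal kernel therefore estimates the
in-phase region width — the basis of the parameter-recovery test.

## The phantom: what it emulates and what it does not

`generate_phantom()` renders gray RGB frames (three identical channels, so
luminance equals the modeled signal) with a vertical vessel strip flanked
by two shadow bands:

| parameter | default | meaning |
|---|---|---|
| `fps`, `duration` | 40 Hz, 10 s | study acquisition (400 frames) |
| `f0` | 1.25 Hz | heartbeat fundamental, 75 bpm |
| `heartbeat_amp` | 3 | parietal luminance swing |
| `harmonic_ratio` | 0.3 | second harmonic at 2.5 Hz |
| `thrill_freq`, `thrill_amp` | 6.25 Hz, 1 | vessel-only thrill tone |
| `vessel_halfwidth` | 56 px | in-phase width 113 px |
| `shadow_halfwidth` | 30 px | each lateral anti-phase band |
| `shadow_gain` | 1 | shadow amplitude equals parietal amplitude |
| `baseline`, `noise_sigma` | 120, 2 | mean luminance, per-pixel noise SD |

Choices made where the design was genuinely open:

* **On-grid tones.** 1.25 Hz and 6.25 Hz fall exactly on the 256-point FFT
  grid at 40 fps. The noise band is defined so that thrill energy cannot
  enter it; an off-grid phantom tone would leak rectangular-window sidelobe
  power into 10&ndash;19 Hz, an artifact of windowing rather than the
  physics being emulated, so the grid-aligned defaults are the faithful
  choice (and keep spectral test oracles exact).
* **Unit shadow gain.** The reversed-phase waveform observed at the vessel
  periphery has amplitude comparable to the parietal trace, so the default
  anti-phase gain is 1.
* **Geometry.** The 113-px in-phase width mirrors the optimal kernel size
  reported for clinical data, making the phantom's recovery target the
  study-relevant scale. The 221-px frame is the smallest that keeps the
  center ROI inside the valid region of the largest (201 px) kernel.
* **Quantization.** Frames are rounded to 8-bit integers by default, with
  clipping to [0, 255] (validation warns when clipping could occur). A
  float output switch exists because tests of exact spectral identities
  need unquantized traces.
* **Thrill as a tone.** The thrill is modeled as a single vessel-only tone:
  the simplest testable embodiment of a band-limited 5&ndash;10 Hz
  component.

The phantom deliberately omits: skin texture and scattered-reflection
structure, illumination drift unless `drift_amp` is set, camera motion,
vessel curvature, and any relation between fistula pathology and waveform
shape. Passing tests therefore demonstrate that the pipeline recovers known
signal structure under realistic noise, not that it discriminates clinical
conditions.

## Visualization

`band_pass_stack()` isolates 1&ndash;5 Hz luminance change per pixel;
`render_sequence()` quantizes it to 256 color levels with one fixed map for
the whole sequence, so colors are comparable across frames. The default
diverging palette places blue at positive change (the tense, distended
anastomosis) and red at negative change, with the domain symmetrized about
zero (`[-max|v|, +max|v|]`) so no change sits at the palette center. Level
index is `floor(256 * (v - vmin) / (vmax - vmin))` clamped to 0..255
(left-closed bins; the exact midpoint lands on level 128); out-of-domain
values clamp to the end levels. All 256 palette entries are constructed to
be distinct. Quantization is 8-bit; higher depths would only require a
longer palette.

## Cohort summaries

Raw SNAVF values are ratios on an arbitrary scale, so a cohort is balanced
by its average: `normalize_snavf()` maps $v$ to $(v - \bar v)/\bar v$,
giving mean exactly 0, a span from negative to positive, and invariance to
positive rescaling. This relative-deviation rule is an inference from the
way published summaries behave (a raw maximum of 0.18 normalizing to 1.44
implies a raw mean near 0.074, exposed as `implied_mean_raw()`); a z-score
alternative sits behind the `method` argument. `quartile_summary()` uses
half medians: Q2 is the overall median, Q1/Q3 are medians of the lower and
upper halves with the overall median excluded for odd counts
(Moore&ndash;McCabe), and the fourth quartile is reported as the maximum
value, matching the verbal definition used in this field's reporting.

## Problem sizes used in the test suite

Unit tests run on small scenes (9&ndash;61 px frames, 280&ndash;400
frames). The acceptance properties run the study-scale default phantom
(221&times;221, 400 frames, full 101-size sweep) over 20 seeds for the
SNR-curve-shape and width-recovery checks, 50 seeds of 90&times;90 noise
frames for the $1/N^2$ law, and 1000 random lists for the quartile rule —
sizes chosen to make sampling error comfortably smaller than the tested
effects.

## Worked example

```{r example}
library(avfpulse)

ph <- generate_phantom(phantom_config(seed = 1))
lum <- to_channel(ph$stack, "luminance")
sweep <- snavf_sweep(lum, roi = c(111, 111))
sweep
#> <snavf_sweep> 101 kernel sizes 1..201 at roi (111, 111)
#>   SNAVF = 1.894e+05 at optimal N = 113 (fundamental 1.25 Hz)

bp <- band_pass_stack(lum, c(1, 5))
frames <- render_sequence(bp)
write_frames_png(frames[1:8, , , , drop = FALSE], "frames")
```

## Known limitations

* The SNAVF scale depends on the documented power convention; values are
  comparable within this implementation but not across tools with other
  FFT normalizations. Cohort normalization removes the scale.
* The sweep quantifies a single ROI trace per kernel; a `--scan-all`-style
  maximization over the whole valid region is not implemented.
* Only lossless containers (multi-page TIFF, raw-RGB + YAML sidecar) are
  read and written; lossy video must be transcoded first.
* Clinical decision thresholds are out of scope: the statistic quantifies,
  it does not classify.
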