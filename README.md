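# avfpulse

Non-contact assessment of the arteriovenous fistula (AVF) — the surgically
created artery-to-vein anastomosis that gives hemodialysis patients
vascular access — from plain RGB video. Each pixel of a fistula recording
carries a periodic luminance variation: the distending vessel moves its
parietal surface toward the camera while casting a growing lateral shadow,
so the pulse wave appears in-phase over the vessel and in reversed phase
beside it. `avfpulse` turns such recordings into a quantitative condition
measure and a color-mapped hemodynamic video, for clinical engineers and
researchers working on optical vascular-access monitoring.

## The method

1. Convert the RGB stack to luminance (weighted sum `0.299R + 0.587G +
   0.114B`; hue and saturation conversions are provided for channel
   comparison).
2. Denoise with a spatial moving-average filter: an N×N kernel of uniform
   weights slides over each frame. Since every pixel shares the in-phase
   pulse while sensor noise is independent, averaging N² pixels drops the
   noise variance by 1/N² — additive averaging through space.
3. Quantify with the SNAVF statistic. On a 256-point FFT of the trace at
   the region of interest (40 fps, bands with inclusive edges):

   * AVFs = power of the fundamental (largest bin in 1–5 Hz) plus its
     second harmonic (largest bin within one bin of 2·f₀),
   * AVFn = sum of the two largest bin powers in 10–19 Hz (above the
     5–10 Hz thrill band, below the 20 Hz Nyquist limit),

   and over the kernel sweep N = 1, 3, …, 201:

   **SN_AVF = max_N ( AVFs / AVFn )**

   The ratio rises while the kernel fits inside the in-phase vessel region
   and falls once it swallows the anti-phase shadow, so the optimal N also
   estimates the vessel's apparent width.
4. Visualize by band-passing each pixel to 1–5 Hz and mapping luminance
   change onto a 256-level diverging palette (blue = positive change, the
   tense anastomosis; red = negative), with one fixed scale for the whole
   sequence.
5. Summarize cohorts: per-recording SNAVF values are balanced by the
   cohort average, `(v − mean)/mean`, and reported as quartiles with the
   fourth quartile being the maximum.

A seeded synthetic phantom (`generate_phantom()`) reproduces the signal
structure — heartbeat plus vessel-only thrill tone, anti-phase lateral
shadow bands, per-pixel Gaussian noise, 8-bit quantization — so the entire
pipeline is testable without clinical data.

## Worked example

```r
library(avfpulse)

ph  <- generate_phantom(phantom_config(seed = 1))   # 400 frames, 221 x 221
lum <- to_channel(ph$stack, "luminance")
sweep <- snavf_sweep(lum, roi = c(111, 111))        # kernels 1..201 step 2
sweep
#> <snavf_sweep> 101 kernel sizes 1..201 at roi (111, 111)
#>   SNAVF = 1.894e+05 at optimal N = 113 (fundamental 1.25 Hz)
```

The optimal kernel (113 px) recovers the phantom's 113-px in-phase vessel
width, and the detected fundamental (1.25 Hz) is the phantom's 75 bpm
heartbeat. The SNAVF value is the signal-to-noise power ratio at that
kernel; on this nearly noise-free phantom it is large, whereas real
recordings with scattered-reflection noise give values of order 0.1.
The reversed-phase check and the color-mapped rendering:

```r
lateral <- extract_trace(lum, c(111, 111 + 56 + 15))
parietal <- extract_trace(lum, c(111, 111))
phase_opposition(parietal, lateral)   # near -1: anti-phase shadow
#> [1] -0.8562536

bp <- band_pass_stack(lum, c(1, 5))
frames <- render_sequence(bp)         # (t, row, col, RGB), global scale
write_frames_png(frames, "out/frames")
```

A command-line wrapper over the same functions ships in
`inst/cli/avfpulse.R`:

```sh
Rscript inst/cli/avfpulse.R simulate --out-dir out --seed 7
Rscript inst/cli/avfpulse.R quantify --input out/phantom.raw \
    --out-dir out/quant --roi 111,111 --kernel-sweep 1:201:2 \
    --bands 1:5,10:19 --fft 256
```

See `vignettes/avf-pulse-quantification.Rmd` for the full account of the
model, parameter defaults, numerical conventions and limitations.

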