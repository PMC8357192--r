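# flimcart

Analysis pipeline for fiber-based fluorescence lifetime imaging (FLIm)
of articular cartilage, aimed at detecting glycosaminoglycan (GAG) loss —
the earliest compositional marker of osteoarthritis — in depth-resolved
cross-sectional scans. It is written for instrumentation and
biophotonics groups who need a tested, reproducible reference for the
full computational chain between a raw multiplexed detector trace and a
segmented GAG-depletion map.

## What it computes

A FLIm scan delivers one digitized record per pixel containing three
time-shifted spectral-channel decays (375–410, 450–485, 530–565 nm,
separated by delay fibers). Per channel the observation is
`y = iRF * h + noise`, with the instrument response dominated by a 600-ps
excitation pulse. The pipeline:

1. **Demultiplexes** each record into three baseline-subtracted channel
   decays (`demultiplex`, `scanBaseline`).
2. **Deconvolves** the iRF by non-negativity-constrained least squares on
   a discrete Laguerre basis (`laguerreBasis`, `deconvolve`): an
   active-set QP solves `min_c ||iRF * Bc − y||²` subject to `(Bc)_n ≥ 0`.
   From the fitted impulse response it derives the average lifetime
   `τ̄ = Σ t h(t) / Σ h(t)` and the integrated intensity.
3. **Assembles maps** of lifetime, intensity and intensity ratio
   (channel / three-channel sum) with a validity mask (`buildMaps`,
   `exportMaps`).
4. **Detects the cartilage surface** at the maximum depth-gradient of
   total intensity, computes Euclidean distance-to-surface per pixel and
   depth-resolved lifetime profiles (`detectSurface`, `distanceMap`,
   `depthProfile`).
5. **Segments the GAG-depleted layer** by thresholding the channel-1
   intensity ratio (default 0.25, re-derivable by ROC analysis), measures
   its thickness, and compares treatment groups by one-way ANOVA with
   Tukey HSD (`segmentDepletion`, `rocThreshold`, `roiSummary`,
   `compareGroups`).

Because no measured data ship with the package, a synthetic phantom
generator (`makePhantom`) produces scans with known ground truth that
encode the study conditions: a channel-1 lifetime ramp (5.7 → 6.1 ns over
0.5 mm of depth), healthy channel-2/3 lifetimes of 6.34 / 5.22 ns that
drop by 0.44 / 0.75 ns under GAG depletion, intensity-ratio changes of
−37% / −31% / +23%, and depleted layers of 0.3 / 0.7 mm for the low /
high enzyme treatments.

## Worked example

```r
library(flimcart)

cfg  <- acquisitionConfig(seed = 2L)          # 50 x 50 px @ 0.2 mm, 40 dB
ph   <- makePhantom(cfg, tissuePreset("high"))
maps <- buildMaps(ph$scan)                    # demux + deconvolve + ratios
surf <- detectSurface(maps)
seg  <- segmentDepletion(maps, surf, threshold = 0.25)
seg
#> SegmentationResult: mean depleted thickness 0.700 mm (threshold 0.25)

roi <- roiSummary(maps, depletedMask(ph$truth))
round(roi$meanLt, 2)
#> [1] 5.98 5.90 4.46
round(roi$meanRatio, 3)
#> [1] 0.203 0.046 0.750
```

(Channel 1 averages 5.98 ns here because the depleted ROI spans the
superficial ramp, 5.7–6.1 ns.)

The segmentation recovers the generator's 0.7 mm depleted layer to the
pixel; the depleted-ROI lifetimes land on the depleted presets
(channel 2: 5.90 ns, channel 3: 4.47 ns) within the per-pixel noise, and
the ratio triple matches the depleted simplex point (0.203, 0.046,
0.750).

A thin command-line front end for the same steps lives in
`inst/scripts/flimcart.R` (`phantom`, `run`, `segment` subcommands).

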