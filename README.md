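# octmorph

Interface detection and surface morphometry for 3D OCT volumes of layered
samples — in particular tissue-engineered (artificial) skin cultured at an
air–liquid interface, where thickness and surface roughness track growth and
keratinisation non-invasively.

## What it computes

OCT A-scans of a layered sample carry peaks at the air–tissue and lower
interfaces, confounded by speckle, stratum-corneum multi-spikes and a
basement-membrane echo. `octmorph` locates the interface pair in every
A-scan with a two-stage search:

1. **Coarse:** among the strict local maxima of the windowed A-scan, the
   brightest peak is paired with the brightest remaining peak at least
   `T1` pixels away (`T1` encodes the minimum plausible sample thickness
   and rejects split peaks from a single interface).
2. **Fine:** each index moves to the *shallowest* local maximum within its
   half-range whose intensity is within `T2` (default 20%) of the coarse
   peak — rejecting sub-surface corneum spikes and membrane echoes.

From the interface map (Pu, Pb per lateral cell) it derives:

* **Thickness** `Th = δ·N/γ` (µm), with `N = Pb − Pu`, `δ` the in-air
  axial pitch and `γ` the refractive index (e.g. δ = 3.5 µm, γ = 1.38
  gives 2.54 µm of tissue per pixel);
* **Areal roughness** over the `PN` valid cells strictly inside a circular
  ROI, after bivariate-cubic flattening of tilt and bow (optional for
  already-level plate samples):

  `Ra = (1/PN) Σ |Zₙ − Z̄|`,  `Rq = √((1/PN) Σ (Zₙ − Z̄)²)`,
  `Rsk = (1/Rq³)(1/PN) Σ (Zₙ − Z̄)³`;

* **Verification statistics** against nominal roughness plates (max
  deviation, relative error at the maximum, OLS sensitivity slope);
* **Longitudinal ANOVA** (one-way repeated-measures across culture days,
  one-way between batches) with `fTailProbability()` to check printed
  (F, df) pairs.

A seedable phantom generator (groove plates with analytic Ra, skin-like
random fields with controlled Ra/skewness, full A-scan signal model with
speckle-like confounders) provides exact ground truth for every stage.

## Worked example

Render a calibration-plate phantom (nominal Ra 1.6 µm triangle grooves),
detect both interfaces and measure roughness and thickness:

```r
library(octmorph)

g  <- AcquisitionGeometry(nX = 64, nY = 64, nZ = 256, axialPitch = 0.25)
up <- makePlateSurface("triangle", targetRa = 1.6, groovePitchUm = 180,
                       gridDim = c(64, 64), lateralPitch = 9)
depth <- 22.4 - (up - mean(up))               # place the surface mid-window
ph  <- renderVolume(depth, depth + 15, g, SignalModel(seed = 1))

roi <- ROISpec(1, 256, 1, 64, 1, 64, center = c(32.5, 32.5), radius = 28)
ifm <- extractSurfaces(ph$volume, roi, DetectionParams(t1 = 10))
#> extractSurfaces: 2472/2472 A-scans valid inside the ROI circle

roughness(surfaceHeights(ifm, g), roi, flatten = FALSE)
#> RoughnessResult: Ra = 1.59 um, Rq = 1.849 um, Rsk = 0.1281 (PN = 2472)

thicknessMap(ifm, g)
#> ThicknessMap: 2472 valid cells, mean Th = 10.87 um (sd 0.00)
```

The measured Ra of 1.59 µm recovers the 1.6 µm target (the phantom's
15 µm optical gap reads as 15/1.38 = 10.87 µm of tissue, uniformly, so the
thickness SD is 0). Verification against a four-plate calibration set:

```r
verificationStats(c(1, 1.6, 3.2, 5.8), c(1.35, 1.92, 3.14, 5.16))
#> $maxDeviation        0.64          # µm, at the 5.8 µm plate
#> $relativeErrorAtMax  11.03         # percent
#> $olsSlope            0.786         # sensitivity (1 = ideal)
```

A thin CLI wraps the same functions
(`inst/scripts/octmorph <simulate|detect|quantify|verify|compare|run>`).

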