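---
title: "Hue spectra fingerprinting: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hue spectra fingerprinting: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(huespectra)
```

## The model

Color change is the primary visible signature of ripening: chlorophyll
breakdown and carotenoid/anthocyanin accumulation move fruit surfaces from
green toward yellow, orange and red. A machine-vision system records this
as 24-bit RGB. `huespectra` condenses each image into a *hue spectrum* — a
saturation-weighted histogram of hue angle — in three steps.

**1. Chromatic projection.** Every pixel maps to the chromatic plane

$$x = R - \tfrac{1}{2}(G + B), \qquad y = \tfrac{\sqrt{3}}{2}(G - B),$$

the plane orthogonal to the gray axis of the RGB cube. Hue is
$H = \operatorname{atan2}(y, x)$ in degrees (corrected by +360 into
$[0, 360)$; 0° red, 60° yellow, 120° green, 240° blue), and saturation is
the normalized chroma $S = \sqrt{x^2 + y^2}/255 \in [0, 1]$. The
projection is invariant to adding a constant to all channels, so lightness
is discarded by construction; grays of any brightness have $S = 0$.

Saturation is defined as the plain Euclidean distance divided by 255.
With this definition the six chromatic corners of the RGB cube (red,
green, blue, yellow, magenta, cyan) all reach exactly $S = 1$ (255 on the
byte scale), consistent with the reference values the package tests pin
down. A variant with a leading factor of 2 circulates in print but would
push pure red to 510 on the byte scale, contradicting those same reference
values; we treat it as a typesetting artifact and do not implement it.

**2. Threshold and binning.** Pixels with $S > t_v$ (strictly greater;
default $t_v = 0.05$) contribute their saturation — not a count — to the
bin of their hue rounded to the nearest integer degree, with degree 0
folded into bin 360 so that red occupies the top bin. Rounding is
half-away-from-zero to match the integer conversion of the original
numerical environment (R's `round()` is banker's rounding and would
disagree at exact half-degrees).

**3. Normalization.** The 360-vector is divided by the number of
contributing pixels, making spectra of different-sized images comparable.
With zero or one contributing pixel the spectrum is defined as all-zero
rather than an error. Two divisor conventions exist: dividing by the
above-threshold pixel count (the runnable published definition) or by the
total pixel count. The first is the default (`normalization =
"included"`); the second is exposed as `"total"`. Under `"included"` a
spectrum's element sum equals the mean saturation of contributing pixels,
so a half-red/half-white image and a fully red image yield identical
spectra; under `"total"` the background fraction rescales the spectrum.

Because neutral backgrounds (white, gray, black) have near-zero
saturation, they fall below $t_v$ and vanish from the spectrum — the
background is removed with no segmentation step. This is the property that
makes the descriptor practical: the same fixture disk yields bit-identical
spectra on white, 50% gray and black backgrounds (a package test and the
acceptance script both verify this to 1e-9 per bin).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `threshold` ($t_v$) | 0.05 | normalized saturation | Real white backgrounds pick up small non-zero saturation from sensor noise and imperfect white balance; 0.05 removes them while keeping any visibly colored pixel. Raising it never admits more pixels (tested monotone). |
| `normalization` | `"included"` | — | The runnable definition of the method; `"total"` kept for comparability with the verbal description of the normalization. |
| crop range (`cropSpectrum`, `--range LO:HI`) | full circle | degrees | Restricting to the color range a produce actually traverses (e.g. red–green for cherries, wrapped ranges allowed since red straddles 360/1) concentrates the signal; PQS responds more sensitively on an optimized range. |
| `ncomp` (PLS) | auto | components | When unset, the count minimizing leave-one-out RMSE on the calibration set, capped at 10 — a conventional guard against overfitting collinear spectra. |
| validation split | random 70/30, seeded | — | No canonical split exists for this method; the seed is recorded in every report, and leave-one-out and explicit calibration indices are offered. |

## PQS compression

The spectrum drawn as a polar figure (radius $V_i$ at angle
$i\alpha$, $\alpha = 2\pi/360$) is compressed to the gravity point of that
figure by triangular decomposition:

$$T = \tfrac{1}{2}\sum_i V_i V_{i+1} \sin\alpha,\qquad
\mathrm{PQS}_x = \frac{1}{6T}\sum_i \left[V_i\cos(i\alpha) +
V_{i+1}\cos((i+1)\alpha)\right] V_i V_{i+1}\sin\alpha,$$

and analogously for $\mathrm{PQS}_y$. Each term is the signed area of the
origin-anchored triangle over one bin pair times its centroid, so the
formula is exactly the area-weighted centroid of the polygon with vertices
$(V_i\cos i\alpha,\, V_i\sin i\alpha)$ — the package tests verify
agreement with an independently coded shoelace centroid to 1e-9.

Design choices the defining equations leave open:

* **Closure.** For the full hue circle the pair (360, 1) is included: the
  figure is closed, and closure is what makes a circular shift of the
  spectrum rotate the PQS point by exactly the shift angle (tested).
* **Cropped ranges.** `pqsPointInRange()` sums only consecutive pairs
  inside the range — an open fan, with no closing edge through the
  excluded arc and no rescaling of $\alpha$. Rescaling the cropped arc
  onto the full circle is left as future work.
* **Degeneracy.** A figure with no two consecutive non-zero bins has zero
  area; its gravity point is reported as a dedicated
  `huespectra_undefined_pqs` error (the CLI emits an `NA` row with a
  reason) rather than a numeric result. Zero-radius vertices contribute
  zero-area triangles and need no special-casing.

## Chemometrics

`fitPLSR()` implements PLS1 (NIPALS with deflation) on mean-centered
predictors; variance scaling is optional and off by default because
spectrum bins share one unit. At full predictor rank PLS1 reproduces
ordinary least squares, which the tests exploit as an oracle; predictions
also agree with an independent PLS implementation (mixOmics) to 1e-8.
`fitMVR()` is ordinary least squares on the six RGB summary statistics
(channel means and population SDs) — the conventional baseline the
spectrum approach is compared against.

Metrics: $R^2 = 1 - SS_{res}/SS_{tot}$ on the calibration and held-out
sets (so validation $R^2$ may be negative), and RMSE% defined as
$100\cdot\mathrm{RMSE}/\overline{y}_{measured}$. The mean-of-measured
denominator is a deliberate choice: per-sample relative errors blow up
when a measurement is near zero.

## The synthetic generator: what it does and does not show

No public image/reference dataset accompanies this method, so the package
generates its own ground-truthed inputs:

* `renderScene()` rasterizes colored disks/rectangles on a neutral canvas
  without anti-aliasing, so included-pixel counts are exact integers and
  the spectrum of a noiseless scene can be predicted in closed form.
  Optional i.i.d. Gaussian channel noise (clipped to [0, 255]) exercises
  threshold robustness; it is *not* a camera model.
* `ripeningSeries()` renders disks whose dominant hue interpolates from
  green (120°) to red (0°) while saturation rises from 0.60 to 0.90 —
  red pigmentation saturating as green tissue ripens — on a 64×64 canvas
  with disk radius 24. A 20° linear hue gradient across the diameter gives
  each spectrum a smooth unimodal bump, as real fruit with color gradients
  show, and lets a linear model interpolate between neighboring ripeness
  states. A narrow exact-color core (1/8 of the radius around the center
  column) pins the dominant bin to the nominal hue, which 8-bit rounding
  of the flank colors would otherwise jitter by a degree or two.
* `syntheticRegressionSet()` pairs each spectrum with a TSS-like response
  $8 + 10u$ (percent, $u \in [0,1]$ the ripeness index — spanning a
  plausible 8–18% soluble-solids range) plus Gaussian noise.

Problem sizes used throughout the tests and the acceptance script — 60
samples, 64×64 images, 50 random oracle images, 100 random PQS spectra —
are the package's chosen desk-scale study conditions.

Passing tests on these fixtures demonstrate algorithmic correctness
(agreement with naive transliterations and closed forms, invariances,
recovery of a known monotone link between peak location and response).
They do not demonstrate field performance: real produce has specular
highlights, shading, within-batch biological variance and camera effects
(gamma, white balance, illumination color) that the generator deliberately
omits and the method itself does not correct for. Published figures of
merit on real cherry or pepper data cannot be reproduced here because
those images and reference measurements are not public; the package
instead checks the qualitative claim that spectrum-based PLSR calibrates
at least as well as the RGB-statistics MVR baseline on identical synthetic
samples and splits.

## Numerical choices and degenerate inputs

* All arithmetic in double precision; integer channels widened before
  subtraction. 16-bit images are rejected unless the caller explicitly
  asks for rescaling; alpha channels are stripped with a warning;
  grayscale input raises a dedicated non-color-image error.
* Hue at the chromatic origin is defined as 0°; harmless, since such
  pixels have $S = 0$ and never pass the threshold. Hues that round to
  exactly 360 in floating point are folded to 0 to keep the $[0, 360)$
  contract.
* Peak finding treats the spectrum circularly (bin 360 adjacent to bin 1);
  plateau maxima are reported once at the lowest degree of the plateau,
  and FWHM is measured by linear interpolation on each flank with a
  circular search, capped at half the circle per flank if the half-max
  level is never crossed. A constant spectrum has no local maximum and
  returns an empty peak table.
* Spectrum CSVs label rows by degree (1–360) to avoid off-by-one
  ambiguity and store values with 15 significant digits; round trips are
  lossless past 12 digits. The CSV dialect is fixed (comma, `.` decimal,
  UTF-8, header) regardless of locale.

## Known limitations

* Hue/saturation here are computed from device RGB, not CIE L\*a\*b\*;
  values are comparable within one imaging setup but not colorimetrically
  absolute.
* Very dark images compress the chromatic plane and degrade hue
  resolution; the method ignores lightness and cannot flag this itself.
* The PLS component-count selector (LOO RMSE, cap 10) is a pragmatic
  default, not an optimality claim; for small calibration sets the cap
  binds first.
* PQS on a cropped range depends on the open-fan convention described
  above; results are not comparable with a rescaled-arc variant.
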