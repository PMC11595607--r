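---
title: "How spherequant detects and measures cell-derived spheres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How spherequant detects and measures cell-derived spheres}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spherequant)
```

## The problem

Sphere-formation assays grow stem-like cancer cells in suspension; the
number and size of the resulting spheres read out stemness and treatment
response. Counting and outlining spheres by hand in brightfield or
phase-contrast images is slow and operator-dependent, and images vary a
lot: multiwell plates give roughly uniform backgrounds, while microfluidic
chambers add illumination gradients, dark chamber-wall shadows, and debris
such as erythrocytes. `spherequant` automates detection, deterministic
numbering, counting, and calibrated area measurement (µm²), and ships a
seeded synthetic-image generator so every stage can be validated against
pixel-exact ground truth without any real data.

## Pipeline

Each image goes through five stages.

1. **Contrast homogenization** — CLAHE followed by Gaussian smoothing.
   CLAHE equalizes each tile of a grid with a clip limit so flat-tile
   noise is not amplified, and interpolates bilinearly between tile
   mappings. Our mapping sends a histogram bin to its *mid-CDF* value
   (the mean of the inclusive and exclusive cumulative distribution),
   which has two useful fixed points: a constant image maps to itself,
   and as the clip limit tends to zero the clipped histogram tends to
   uniform, so the output approaches the input up to bin quantization.
2. **Texture response** — a Gabor filter bank, the Cartesian product of
   frequencies `f = 1/4, 1/6, 1/8` cycles/px and six orientations in 30°
   steps, with envelope sharpness `gamma = 10` (major axis) and
   `eta = 0.5` (minor axis) on a 21-px grid: 18 complex kernels. Each is
   convolved with the image; the per-pixel maximum of the magnitudes is
   the aggregate texture response. Max pooling over the bank makes the
   response approximately rotation- and scale-invariant over the covered
   grid.
3. **Region proposal** — the aggregate response is thresholded at the
   *local mean plus 5% of the global response range*. The local-mean
   comparison gives illumination invariance (the bank has non-negligible
   DC gain, so flat regions respond in proportion to their luminance);
   the range-proportional margin guarantees a flat image proposes
   nothing. The thresholded map is closed and dilated, 8-connected
   components are taken, boxes are padded and clipped, and two guards
   drop non-sphere structure: boxes smaller than
   `max(16, min(height, width)/64)` px per side (the resolution rule) and
   components filling less than 15% of their bounding box (thin
   chamber-wall rings).
4. **Per-region segmentation** — inside each region the Otsu threshold
   (256-bin histogram, between-class variance, lowest-threshold
   tie-break) splits intensities; the foreground class is chosen by
   polarity. `"auto"` polarity uses the region's 1-px border frame: since
   regions are padded, the class dominating the frame is background.
   Sobel edges (the two 3×3 kernels, gradient magnitude thresholded by a
   second Otsu pass) are united with the intensity mask, and the union is
   closed and dilated with a 2-px disk.
5. **Measurement, filtering and numbering** — 8-connected components of
   the cleaned union define objects and duplicate merging (overlap
   > 50% IoU across regions, or > 50% of the smaller object, keeps the
   larger). Each component's **area, centroid and contour are measured on
   the hole-filled Otsu intensity support inside the component**, not on
   the dilated union: the edge band and final dilation exist to connect
   core and rim fragments, and measuring on them would inflate every
   radius by the structuring-element radius plus the edge-band width — a
   21% area error at radius 10 px from a single pixel of bias. With the
   intensity-support rule the measured area of a synthetic disk matches
   the pixel-exact ground truth. Because the dilated union can also
   bridge *neighboring* spheres whose cores are clearly separate, each
   connected fragment of the intensity support is emitted as its own
   detection (the giveaway of a wrongly merged pair is a "circularity"
   above 1 — two discs' area over one disc's perimeter). When the
   intensity support inside a component is empty (e.g. a pure edge ring),
   the eroded, hole-filled component is the fallback. Objects below the area floor or the
   circularity floor (`4πA/P²`) are discarded as debris; survivors are
   numbered 1..N in raster order of their centroids (row, then column;
   ties to the larger object), so a chamber imaged across days keeps
   stable sphere identities.

For the same reason as in stage 5, thresholding for quantification runs on
the *original* intensities: CLAHE's nonlinear remap (and smoothing against
an asymmetric background) shifts the apparent boundary and biased measured
areas by 5–11% in our synthetic benchmarks. The homogenized image drives
texture response and region proposal only.

## Calibration

Areas are converted as `area_um2 = area_px × (µm/px)²`. The physical pixel
size depends on the objective *and* the camera sensor, so it is required
user input (`--um-per-px` or a config key), never a silent default; the
shipped `config_template.cfg` marks its calibration values as
placeholders. The magnification label is carried into every CSV row so
downstream statistics can stratify by lens.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `clahe_clip_limit` | 0.01 | fraction of tile pixels | mild equalization; avoids noise amplification |
| `clahe_tile_grid` | 8×8 | tiles | standard grid; falls back to global when larger than the image |
| `gaussian_sigma` | 1.0 | px | denoise without erasing sub-10-px structure |
| Gabor `f` | 1/4, 1/6, 1/8 | cycles/px | rim scales at the supported magnifications |
| Gabor orientations | 0–150° step 30° | — | closed under 90° shifts |
| Gabor `gamma`, `eta` | 10, 0.5 | — | elongated rim-following envelope |
| `roi_padding_px` | 12 | px | margin so objects do not touch region borders |
| `min_sphere_area_um2` | 300 | µm² | debris floor (erythrocytes are far smaller than spheres) |
| `min_circularity` | 0.4 | — | crystals/wall fragments are elongated |
| `struct_element_radius_px` | 2 | px | connects core and rim without merging neighbors |
| `adaptive_block_fraction` | 1/8 | of min side | local-mean window for adaptive thresholding |
| `sphere_polarity` | auto | — | border-frame rule; override for known polarity |

The size and circularity floors are deliberate extensions: debris,
erythrocytes and crystals are known failure modes of intensity-based
sphere counting, and no printed rule exists for rejecting them, so both
floors are exposed and documented rather than hard-coded.

## The synthetic generator

`scene_spec()` / `generate_scene()` render spheres as bright discs with a
gentle radial shading and a dark halo annulus *outside* the disc support,
mimicking the phase-contrast halo that surrounds (not overlaps) an object.
The ground-truth mask of a sphere is exactly the set of pixels whose
center lies within the stated radius, so truth areas agree with an
independent pixel-distance oracle by construction and differ from `πr²`
only by the discretization bound `4πr + 4`. Two regimes are generated:
`uniform` (flat background, the multiwell-plate case) and `microfluidic`
(linear illumination gradient, a dark Gaussian-profile chamber-wall ring,
and clusters of 2–4 px erythrocyte-like specks at sphere-like intensity).
All randomness — placement, artifacts, noise — is fixed by one seed, and
the generator restores the caller's RNG state.

Defaults were chosen once to represent realistic acquisitions: background
0.45, sphere core 0.85 with halo 0.25 (≈ 2:1 object contrast), radii
12–24 px (24–48 µm diameters at 1 µm/px), additive Gaussian noise
σ = 0.01 (≈ 1% of full scale). `noise_sigma` is the difficulty knob:
detection F1 on a fixed scene degrades monotonically as it rises.

What the generator does **not** emulate: out-of-focus blur and PSF
effects, agglomerated/touching spheres, vignetting, sensor artifacts, and
real debris morphology. Passing the synthetic benchmarks therefore shows
the pipeline recovers disc-like objects over the two background regimes at
realistic noise — not that it matches expert annotation on any particular
instrument's images, which always requires a calibration check on real
data.

## Numerical choices

- Histograms use 256 bins on `[0, 1]`; Otsu returns a *bin-edge*
  threshold with ties broken low, so thresholds are deterministic and
  shift exactly with whole-bin intensity translations.
- Convolution is true convolution via FFT with mirror padding (reflective
  borders everywhere); "zero" assertions are made at 1e-12 because FFT
  leaves ~1e-16 residuals. Gaussian kernels are truncated at 4σ and
  normalized.
- Connected components are 8-connected (a 4-connected labeling is merged
  across diagonal touches with a union–find pass).
- The structuring element is a disk; one closing and one dilation —
  minimal iterations so adjacent spheres do not merge.
- Degenerate cases are defined, not accidental: a constant region yields
  zero detections, an empty region list is valid, closing/dilation of an
  empty mask is empty, and raster-order numbering breaks centroid ties by
  area so label assignment is permutation-stable.

## Validation problem sizes

The shipped tests and the acceptance script validate on: 200 random
12×12 8-level images against an exhaustive Otsu maximizer; 50 seeded
256×256 uniform-background scenes with 1–12 spheres (count recovery);
single-disk scenes at radii 10–28 px (area recovery within 10% of `πr²`,
measured bias < 1%); five 512×512 scenes with 1–40 spheres (total area
monotone in content, R² of the linear fit ≈ 0.96–0.99); ten microfluidic
scenes of 4 spheres (recall ≥ 0.8 at default config, precision allowed to
degrade); and two repeated batch runs over a 3-image dataset
(byte-identical CSVs).

## Known limitations

- Touching or agglomerated spheres are detected as one object; no
  watershed split is attempted.
- The Gabor bank's DC gain means bright flat regions respond in
  proportion to luminance; region proposal compensates with local-mean
  thresholding, but the raw aggregate response is not
  illumination-invariant on its own.
- No flat-field or illumination-surface correction is applied; strong
  uncorrected vignetting can push the per-region histogram away from
  bimodality.
- `"auto"` polarity assumes objects do not dominate a region's border
  frame; fields containing a single object larger than its padded region
  should set the polarity explicitly.
- The area floor is calibrated in µm², so an implausible
  microns-per-pixel value silently rescales the debris filter — another
  reason calibration is mandatory input.
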