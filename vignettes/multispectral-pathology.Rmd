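---
title: "Multispectral segmentation and nucleocytoplasmic-ratio analysis of skin sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multispectral segmentation and nucleocytoplasmic-ratio analysis of skin sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cutaneous squamous cell carcinoma (cSCC) is diagnosed from H&E-stained
sections, where two features dominate: the nucleocytoplasmic ratio rises
sharply in malignant epithelium, and well-differentiated cSCC forms keratin
pearls. Narrow-band multispectral microscopy separates these structures
without extra staining, because each stained component absorbs most
strongly in a different part of the visible spectrum: hematoxylin-stained
nuclei darkest near 660 nm, keratin and large lipid droplets near 600 nm,
collagen and diseased epidermis near 520 nm. `msipath` implements the full
measurement chain — reflectance calibration, band-wise segmentation,
window-based ratio quantification, and group statistics — plus a
ground-truthed synthetic scene generator so the chain can be validated end
to end without slide data.

```{r}
library(msipath)
res <- run_cohort(n_per_group = 21, seed = 1)
report_cohort(res)
```

## Calibration model

Raw frames are integer sensor counts. Per band, the pipeline applies, in
acquisition order:

1. **Frame averaging.** Each band is exposed `n_frames = 5` times; the
   per-pixel mean suppresses read noise by `sqrt(5)`.
2. **Reflectance correction.**
   `R(lambda) = (I_raw(lambda) - I_dark) / (I_ref(lambda) - I_dark)`,
   with `I_dark` the unilluminated dark frame and `I_ref` a blank-slide
   frame per band. Pixels whose denominator falls below `eps = 1` count are
   unusable (no effective illumination): they are zeroed and counted in the
   cube provenance. Results are clipped to [0, 1] — downstream thresholds
   assume a bounded range, and specular or noise excursions outside it are
   uninformative. Because the reference frames see the same optical train
   as the sample frames, this step also removes the instrument vignette.
3. **Adaptive two-dimensional gamma illumination correction.** The
   illumination surface `F(x, y)` is estimated as a wide Gaussian blur of
   the image (default scale: image width / 8), and each pixel is raised to
   `gamma(x, y) = base^((m - F(x, y)) / m)`, `m = mean(F)`, `base = 0.5`.
   Dark regions are brightened, bright regions darkened, and a uniform
   image passes through unchanged. The single-scale form was chosen for
   its transparency; `base` and the scale are configurable, and the whole
   step can be disabled (`gamma = NULL`) for optics known to be flat —
   with no vignette and no noise the calibration then inverts the forward
   model exactly, up to count quantization (half a count over
   `ref_level - dark_level`).

*Numerical choice.* For scales of 16 px and above, the Gaussian estimate is
computed on an 8x-decimated copy (sigma scaled to match) and bilinearly
upsampled. For an illumination-scale surface the difference is far below
the sensor noise floor, and the cost drops by an order of magnitude.

## Segmentation

Each working band (660 / 600 / 520 nm) is enhanced and thresholded
independently:

1. **Contrast-limited local histogram equalization** (8x8 tiles, clip limit
   0.01 as a fraction of tile pixels per histogram bin) raises nuclear
   contrast without amplifying flat-field noise unboundedly. Constant
   images pass through unchanged; image sizes that are not multiples of the
   tile grid are symmetrically padded and cropped back.
2. **Median filtering** (3x3, reflective padding) removes salt-and-pepper
   noise.
3. **Adaptive mean thresholding**: the local threshold is the mean over a
   51x51 neighbourhood (reflective padding), and a pixel joins the mask
   when it is darker than its threshold by `offset = 0.02` reflectance
   units. Structures are the *dark* (strongly absorbing) pixels because
   stained chromophores absorb at their signature band. The local mean is
   computed **over tissue pixels only**: blank glass at the section border
   is roughly twice as bright as tissue, and including it drags the local
   mean up and paints a spurious ~25 px "dark" halo along the tissue edge
   at every band. Restricting the statistic to the tissue support removes
   the artifact while leaving the plain (unsupported) operator, and its
   exact brute-force semantics, untouched.

A pixel captured at more than one band is assigned the class at whose band
it reflects *least*, with ties broken nuclei > keratin > collagen. Pure
precedence is not enough here: absorbance peaks have finite spectral width,
so collagen also dips at 600 nm and keratin at 660 nm. Under blind
precedence the collagen texture of healthy dermis is mislabelled keratin —
at which point every analysis window fails the keratin-junction filter and
normal sections yield nothing. The spectral argmin keeps each class at its
own band, and sends keratin-pearl rims picked up at 660 nm back to the
keratin mask, which is exactly what makes the junction-window exclusion
effective. The tissue mask itself is the median-filtered 520 nm band below
`blank_threshold = 0.95` — above the reflectance of any stained tissue
(cytoplasm sits near `exp(-0.1) = 0.905`), below the ~1.0 of glass.

## Window quantification

A 100x100 px window slides at 50 px stride (half-window, so junctions
between grid cells are also seen). Windows are excluded when their mean
660 nm reflectance is below 0.15 (underexposed) or above 0.95 (mostly
blank), when keratin occupies more than 10% of the window (nucleus/pearl
junction), or when less than half the window is tissue. From the eligible
set, five windows are selected greedily by descending tissue coverage,
ties broken row-major, skipping any window that overlaps an already chosen
one — deterministic and auditable. Per selected window the
nucleocytoplasmic ratio is `100 * nuclear_px / tissue_px`: nuclear area as
a share of *all* tissue in the window. This denominator is robust when no
separate cytoplasm segmentation exists; the strict variant
`nuclear_px / (tissue_px - nuclear_px)` is available via
`window_criteria(denominator = "cytoplasm")`. Each section is summarized by
the mean, maximum and minimum of its five window ratios.

## Statistics

Group comparison uses the classical pooled-variance two-sided Student's
t-test (`df = n_a + n_b - 2`); Welch's variant is a flag away. Degenerate
inputs are defined explicitly (zero variance with equal means: t = 0,
p = 1). Discrimination is quantified by a ROC curve over all distinct
score thresholds with carcinoma as the positive class and higher ratio =
more positive; tied scores enter as one threshold, so the trapezoidal AUC
equals the Mann-Whitney pair statistic (win 1, tie 0.5) over
`n_pos * n_neg`. Exact p-values are reported; no multiplicity correction
is applied across the three summary statistics. All of this runs for each
of mean, max and min via `evaluate_cohort()`.

## The synthetic scene generator

No slide data accompanies the method, so the generator *is* the study
material; its defaults encode the study conditions rather than tunable
knobs.

* **Geometry.** A tissue slab covers ~88% of the 512x640 frame (3% glass
  margin per side). Keratin pearls are discs (2-5 per carcinoma section,
  radius 15-40 px; none in normal skin). Nuclei are randomly oriented
  ellipses — semi-axes 3-6 px in normal tissue, 5-10 px in carcinoma —
  placed uniformly until the nuclear share of tissue reaches the section's
  target; placements into a pearl are rejected, placements crossing the
  tissue boundary are clipped so nuclear density stays homogeneous up to
  the section edge. The per-section bookkeeping is exact; the realized
  fraction lands within 0.003 of the target (the last nuclei shrink as
  needed to make that reachable at any frame size). The remaining tissue is
  split into a smooth collagen texture (30% of it) and cytoplasm.
* **Targets.** Normal sections target a 4.239% nuclear fraction, carcinoma
  15.607% — the two group means the method is expected to recover — with a
  15% relative between-section jitter emulating biological variability.
  Carcinoma nuclei also absorb 1.3x more strongly (larger *and* darker).
* **Spectra.** Each class has a Gaussian absorbance peak (height 1.2, width
  40 nm, baseline 0.1) at its signature band — nuclei 660, keratin 600,
  collagen 520 nm — and reflectance follows Beer-Lambert `R = exp(-A)`:
  bounded, physically motivated, exactly invertible for round-trip tests.
  True H&E absorbance spectra at these bands are not part of the model; the
  peaks exist to realize the band-to-structure mapping, not to be
  photometrically real.
* **Imaging.** `raw = round(clip(ref_level * R * V + dark_level + noise))`
  with `ref_level = 230`, `dark_level = 8` counts, Gaussian read noise
  (sd 2 counts), five frames per band, and a radial cos^4-style vignette
  `V` losing 25% at the far corner. Reference frames are the noiseless
  blank response per band; the dark frame carries noise.
* **Cohorts.** `generate_cohort()` derives per-section seeds from one
  master seed and asserts that the two groups' *true* fractions separate
  completely (regenerating from a derived seed otherwise), so that a
  perfect-AUC result downstream tests the pipeline, not a lucky draw.

What the generator does **not** emulate: histological texture, staining
variability between laboratories, optical blur (class boundaries are
pixel-sharp), chromatic mis-registration, focus errors. Passing tests
therefore show that the measurement chain is correct and unbiased under
the stated optical model — not that segmentation would reach the same
accuracy on real, blurred, variably stained slides.

One consequence of the geometry is worth knowing: pearls both dilute the
section-global nuclear fraction (they are tissue without nuclei) and repel
nuclei from their rims, while the analysis deliberately avoids
keratin-heavy windows — so recovered carcinoma ratios sit slightly above
the section-global truth. That mirrors the method itself, which reads the
ratio away from keratinized areas, and stays within the 15% relative
recovery band the tests enforce.

## Problem sizes and determinism

The validation suite runs the full study at its native conditions — 21
sections per group, 512x640 px, 13 bands, five frames — once, and reuses
that cohort across the end-to-end checks; unit-level properties use
256x320 to 320x400 frames, which are the smallest sizes at which five
non-overlapping 100 px windows remain available around pearls. Every
random draw flows from one master seed through named per-section seeds;
`run_cohort()` twice with the same seed is bit-identical, and selection,
thresholds and tie-breaks contain no hidden randomness. Pixel coordinates
are 0-based row-major in all window tables.

## Known limitations

* Lipid droplets (normal) and keratin pearls (carcinoma) share the 600 nm
  band and one mask; the method does not tell them apart.
* No instance-level nucleus separation is attempted — the ratio is an area
  fraction, not a count.
* The 420-660 nm grid in 20 nm steps is the default wavelength set; other
  grids are accepted as long as the three working bands are present.
* `equalize_local` inherits the canonical tile-interpolated CLAHE; its
  histogram discretization (256 bins) means reflectance values are
  effectively quantized to ~0.004 after enhancement.
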