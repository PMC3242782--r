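---
title: "Methods: image cytometry of chromatin condensation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image cytometry of chromatin condensation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyodens)
```

## The measurement model

Feulgen staining is stoichiometric for DNA, so the optical density (OD)
integrated over a nucleus is proportional to its DNA content. A scanning
microspectrophotometer reports one absorbance per grid point; karyodens
represents this as an `absorbance_image`, a matrix of per-pixel ODs with
a physical pixel pitch (default 0.5 µm, i.e. 0.25 µm² per pixel, the
classical scanning-spot geometry).

Segmentation uses the instrument's background rule: pixels with OD no
higher than the background threshold (default 0.020) are removed, the
survivors are grouped into 8-connected components, and components
smaller than a minimum area (default 50 px) are discarded as debris.
The condensed-chromatin rule is a second, higher OD cutoff (default
0.100): in-nucleus pixels **strictly above** the cutoff operationally
define "condensed" (heterochromatic) texture. The strict inequality on
the cutoff side is a package choice — the background side is "no higher
than", hence `<=` for background and `>` for condensed — and both
thresholds are plain configuration.

Per nucleus we report:

* `A_T` — total integrated absorbance (the Feulgen-DNA value, arbitrary
  units), and `S_T` — nuclear area (µm²);
* `A_C`, `S_C` — the same quantities over the condensed pixels;
* `Ac% = 100·A_C/A_T`, `Sc% = 100·S_C/S_T`;
* `AAR = (A_C/S_C)/(A_T/S_T)` — the average absorption ratio, the
  factor by which mean condensed-chromatin absorbance exceeds the
  whole-nucleus mean. Because the condensed set is exactly the high-OD
  subset, `AAR >= 1` wherever it is defined; when no pixel exceeds the
  cutoff (`S_C = 0`) the ratio is undefined and is reported as `NA` and
  excluded from group statistics rather than forced to a sentinel
  value.

Chromatin decondensation therefore shows up as a *decrease* in Sc%
accompanied by an *increase* in AAR: fewer pixels stay above the
cutoff, but those that do stand out more against the diluted
whole-nucleus mean. The `scatter_diagram()` plane (Sc% on x, AAR on y)
makes this movement visible per nucleus. Named phenotype regions on
that plane are laboratory conventions without an agreed numeric
geometry, so no region map ships by default; users can overlay their
own rectangles.

## Group statistics

`summarize_group()` reports the conventional columns n, X (mean), S
(sample SD, n−1; defined as 0 for a single value) and Md (median,
midpoint rule for even n). `compare_groups()` mirrors common practice
in this literature: a two-sided Student t-test when both samples look
normal, otherwise a two-sided Mann-Whitney test, with significance
declared at P < 0.05. The normality screen is a Shapiro-Wilk test on
each sample at α = 0.05 — the screen itself is a package choice (the
convention names no pre-test), so `force_test` can override it, and the
orchestrated pipeline records which test was used for every variable.
The Mann-Whitney p-value is exact (enumeration of the U distribution)
when the smaller sample has at most 8 observations and there are no
ties; otherwise the normal approximation with tie and continuity
correction is used. Samples outside the Shapiro-Wilk range (n < 3 or
n > 5000) fall back to Mann-Whitney. No multiple-testing correction is
applied anywhere, deliberately.

## Feulgen-DNA C classes

`c_class_histogram()` bins `A_T` values into ploidy classes against a
2C anchor estimated from a calibration population (cells of known
diploid DNA content, or the control class with the smallest values).
Two choices needed fixing:

* **Anchor**: the *median* of the calibration population. A "smallest
  values" anchor is the verbal convention, but a minimum is a
  one-point statistic and fragile against a single dim nucleus; the
  median of a dedicated 2C population estimates the same location
  robustly.
* **Edges**: geometric midpoints between doubling classes — class
  `~(2·2^k)C` spans `[anchor·2^(k−1/2), anchor·2^(k+1/2))`, with
  everything below `anchor/√2` collected in `"<2C"` (subdiploid).
  Geometric midpoints are the natural cutpoints for a doubling series;
  they are config-overridable in the sense that any binning can be
  recomputed from the returned edges.

The classes partition the positive axis, so each nucleus lands in
exactly one bin, and labels are invariant under joint rescaling of the
values and the reference (arbitrary-unit safety).

## TUNEL scoring

TUNEL positivity is quantified by *relative dark-spot area*, not mean
gray, because DAB deposition does not follow Beer-Lambert and mean
gray is therefore not a valid densitometric quantity. Spot pixels are
the in-nucleus pixels whose 8-bit gray value lies in the inclusive
window 60–100; for color input the gray value defaults to Rec.601
luminance (`0.299R + 0.587G + 0.114B`) since the single-channel
convention of the original instrument is not fixed — the channel is
selectable. Ranks follow the relative spot area: 0% negative, (0, 5)%
weak, [5, 50)% moderate, ≥ 50% strong; boundaries are closed on the
lower side, so exactly 5% is moderate and exactly 50% strong.
`positivity_table()` aggregates per condition into the standard
Total/Strong/Moderate/Weak percentage layout.

## The synthetic-nucleus generator

No public microscope data accompany this kind of study, so the
generator is a first-class module whose ground truth drives every
downstream test.

A nucleus is an elliptical mask (semi-major axis `nucleus_radius_px`,
axis ratio 0.8 by default — the eccentricity is a free shape choice,
since only areas, not shapes, are reported in this literature).
Condensed foci are made by thresholding a Gaussian-smoothed seeded
random field (correlation length `focus_scale_px`, default 4 px) at
the quantile that realizes the requested area fraction: the top-k
field pixels become foci, which gives spatially coherent blobs with
exact-by-construction area control (the realized fraction differs from
the request only by one-pixel rounding). Condensed pixels draw OD from
`N(od_condensed, od_noise_sd)` (default mean 0.20), diffuse pixels
from `N(od_diffuse, ·)` (default mean 0.08), and the result is clipped
at 0 because absorbance is non-negative. When `target_iod` is set, the
in-mask ODs are rescaled so their sum equals it exactly, which is how
ploidy mixtures are simulated. Identical parameters and seed give
bit-identical images; population generation derives per-nucleus child
seeds from the population seed.

Defaults were chosen once to make the measured statistics land in the
physiological range of HDAC-inhibitor experiments: with
`od_diffuse = 0.08`, `od_condensed = 0.20` and noise SD 0.01, a
control-like nucleus measures AAR ≈ 1.3 and the 0.100 cutoff
misclassifies only ~2% of diffuse pixels, so measured Sc% tracks the
true condensed fraction within ~1–2 points for radius ≥ 30 px.

The two population presets encode the decondensation contrast:
`control` draws the condensed fraction logit-normally around mean 0.60
and `decondensed` around 0.40 (the direction and rough magnitude of
the median Sc% shift seen under HDAC inhibition), both with SD 0.5 on
the log-odds scale; radii are normal (mean 35, SD 3) truncated at
30 px. The logit-normal keeps fractions in (0, 1) with roughly
symmetric spread around the mean — the published tables only give
summary statistics of derived quantities, so the population dispersion
is an explicit modeling choice, not an estimated one. Note that at a
0.5 µm pitch a 30–40 px radius implies nuclear areas larger than
typical cultured-cell nuclei; the generator trades physical area
realism for accurate area-fraction control, and since all derived
statistics (Sc%, Ac%, AAR) are ratios this does not distort the
phenomenology. `S_T` comparisons on synthetic data are therefore
about internal consistency, not biological area values.

Synthetic TUNEL cells paint an elliptical nucleus in a methyl-green
counterstain tone (luminance ≈ 172, outside the detection window) on a
near-white background, with DAB-brown spots (luminance ≈ 84, inside
the 60–100 window) placed by the same top-k-of-smoothed-field
mechanism. The default simulated conditions draw each cell's rank from
fixed probabilities — control ≈ 6% positive almost all weak, treated ≈
36% positive dominated by weak — sketching the late-treatment pattern
of HDAC-inhibitor TUNEL tables, and then a coverage uniform within the
rank's band.

What the generator does *not* emulate: optics (PSF, glare, focus),
stain kinetics, touching or overlapping nuclei, mitotic figures,
micronuclei and apoptotic morphologies (these are consumed as visual
counts via `cell_class_counts()`, never detected), and stain-color
variability in TUNEL images. Passing tests therefore demonstrate the
correctness of the measurement and statistics machinery on images that
satisfy the two-compartment model exactly — they do not validate
segmentation robustness on real microscope data, where touching nuclei
in particular would require watershed splitting that the package
deliberately does not attempt.

## Numerical and degenerate-input choices

* Background `<=` vs condensed `>`: see above; a pixel at exactly
  0.020 is background, at exactly 0.100 it is non-condensed.
* `Sc% = 100` forces `AAR = 1` exactly (the implementation divides a
  quantity by itself), so the homogeneous-nucleus corner is exact, not
  approximate.
* Transmittance conversion clips intensities at a floor of one count
  before taking `log10(white/I)` and counts the clipped pixels in a
  `saturated_px` attribute; zero transmission would otherwise give
  infinite OD.
* A completely tied Mann-Whitney comparison (all observations equal)
  degenerates the normal approximation; it is reported as P = 1, never
  significant.
* The generator refuses geometrically degenerate requests: masks below
  16 px, or a condensed fraction that rounds to 0 or all of an
  undersized mask.
* The Gaussian smoothing brush is capped at the image size so small
  nuclei remain generable.

## Pipeline determinism and problem sizes

`run_karyometry()` and `run_tunel()` are deterministic given the
config seed (per-stage seeds are derived from it), and each run writes
a JSON manifest echoing the full configuration, package and R versions
and per-stage counts, so a manifest suffices to reproduce a run. The
package defaults follow the classical study design — 200 nuclei per
condition for karyometry and 1000 cells per condition for TUNEL. The
test suite exercises the same machinery at reduced sizes (25–200
nuclei, 60–120 cells) chosen so the whole suite runs in about a
minute; the acceptance properties (oracle equality on 500 random
images, 1000 enumerated Mann-Whitney cases, 200-nuclei preset
recovery, 100-cell TUNEL round-trip) run at full stated sizes.

## Known limitations

* No watershed splitting of touching nuclei; each connected component
  is one nucleus.
* No glare, diffraction or stain-stoichiometry corrections.
* The TUNEL gray window is applied to luminance by default; if a
  camera-specific single channel is intended, set `channel`.
* Phenotype-region geometry on the Sc%–AAR plane ships empty.
* Synthetic nuclear areas are larger than physiological ones at the
  default pitch (see above).
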