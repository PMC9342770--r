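---
title: "Quantifying meiotic foci on the chromosome axis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying meiotic foci on the chromosome axis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiofoci)
```

## The scientific problem

In meiotic prophase I, programmed DNA double-strand breaks (DSBs) initiate
recombination. Cytologically, DSB machinery components (SPO11-1, PRD3) and
DSB markers (RAD51, γH2AX) appear as diffraction-limited immunofluorescent
foci on chromosome spreads, while axis proteins (ASY1, SMC3, REC8) stain
the chromosome axis as a continuous curvilinear structure. Three per-nucleus
quantities carry most of the biology:

1. the **focus count** per nucleus,
2. the **overlap fraction** — the proportion of foci whose signal spatially
   coincides with the axis signal (object-based colocalization), judged
   against a **180° rotation randomization null** that estimates how often
   foci would overlap the axis by chance, and
3. the **on-axis density** — axis-overlapping foci per micrometre of axis,
   which requires measuring total axis length.

Counting and overlap assignment in this field are traditionally manual
(ImageJ counting on deconvolved/raw image pairs; per-cross-section line
profiles in the microscope vendor's software). `meiofoci` replaces those
steps with deterministic, parameterized operators so that the whole chain —
from image to group-level Mann–Whitney–Wilcoxon comparisons — is
reproducible, and validates every stage against simulations with known
ground truth.

## Pipeline overview

| Stage | Function | Method |
|---|---|---|
| Simulation | `simulate_nucleus()` | disc nucleus, repulsive smooth axis paths, planted foci, Gaussian PSF, Poisson + Gaussian noise |
| Focus detection | `detect_foci()` | background subtraction, scale-normalized Laplacian of Gaussian, robust threshold, sub-pixel centroids |
| Axis segmentation | `segment_axis()` | Hessian ridge filter, hysteresis threshold, Guo–Hall thinning, spur pruning, polyline length |
| Colocalization | `score_foci()`, `rotation_null()` | line-profile or distance criterion; point reflection through the nucleus centroid |
| Statistics | `mww_test()`, `compare_groups()` | exact (enumerated, tie-aware) or tie-corrected normal MWW |

Coordinates follow one convention everywhere: 0-based pixel indices with
the pixel-centre mapping `x_um = col * pixel_size_um`,
`y_um = row * pixel_size_um` (in R's 1-based indexing, `col - 1` and
`row - 1`).

## The synthetic nucleus generator

No raw microscopy data accompany the measurements this package models, so
the simulator is the test bed: it provides images whose true focus
positions, on-axis labels and axis length are known exactly.

**What it emulates.** A disc-shaped nucleus (default radius 12 µm) holding
several smooth curvilinear axis paths (default six paths of 36 µm,
totalling ~216 µm — the order of magnitude of the total axis length of an
Arabidopsis meiocyte), `n_foci` diffraction-limited foci (default 180,
matching the reported wild-type leptotene regime of ~179 SPO11-1 foci per
nucleus), an isotropic Gaussian PSF (σ = 0.13 µm), and a widefield camera
noise model: Poisson shot noise on signal plus background, additive
Gaussian read noise, integer digitization. Default calibration is
0.064 µm/px on a 1024 × 1024 field; the imaging system behind the original
measurements does not publish its pixel size, so these defaults are
assumptions chosen to be plausible for 100× widefield imaging, and every
one is overridable.

**Axis paths.** Each path is a smoothed random walk: heading increments are
AR(1)-correlated Gaussian turns, capped at 0.15 rad per 0.1 µm step so the
minimum turning radius (~0.7 µm) stays well above the PSF scale; walks are
steered back from the nucleus boundary and softly repelled by already
placed paths and by their own earlier vertices (summed inverse-distance
weighted repulsion). Candidate paths that still pass within 0.3 µm of
another path or of themselves over more than 2% of their vertices are
redrawn (up to ten times; the closest candidate is kept if none
qualifies). This mutual avoidance is deliberate: distinct chromosome axes do
not run together, and two planted paths that merged under the PSF would
make the planted length ambiguous — the ground truth would not be a valid
oracle for the length measurement. The paths are resampled at 0.1 µm and
trimmed to an exact per-path arc length, so planted length is known to
machine precision. An earlier design (cubic splines through random control
points) was abandoned because uncontrolled path crossings merged in the
rendered image and biased the planted-versus-measured length comparison by
15–25%.

**Foci.** Each focus is on-axis with probability `p_on_axis` (a uniformly
random arc-length position on a length-weighted random path) or otherwise
uniform in the nucleus at distance > 2σ~PSF~ from every path, so planted
labels are unambiguous at the PSF scale. A minimum separation (default
0.52 µm = 4σ~PSF~) keeps planted spots resolvable. The
`uniform_foci = TRUE` mode instead places all foci uniformly over the
nucleus mask — the placement under which the rotation null is calibrated.
`axis_retained_fraction < 1` fragments each path into ~2 µm stretches and
keeps a random subset, emulating the short axis stretches of
cohesin-defective nuclei.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: meiotic-stage chromatin morphology, axis
synapsis (no transverse-filament channel), entangled or touching axes, 3D
structure (a single 2D plane stands in for projected z-stacks),
deconvolution artifacts, chromatic shift, bleaching, and non-uniform
background. Results on real spreads therefore still need visual sanity
checks; the simulations validate the operators, not the microscopy.

## Focus detection

The channel is background-subtracted (Gaussian estimate at 2 µm scale — a
reproducible stand-in for the deconvolution used in manual workflows),
convolved with a negated scale-normalized Laplacian-of-Gaussian kernel at
the PSF scale, and local maxima are kept when the response exceeds
`median + k·mad` of the response (default k = 5). The mad-based rule makes
the threshold adaptive to the image's own noise level; an absolute floor
(10⁻⁶ of the peak response) guards the degenerate noise-free case where
the mad collapses. A minimum separation (default 3 px) is enforced
greedily from the strongest response down, which makes the detected count
monotonically non-increasing in `k`. Centroids are refined by
intensity-weighted means in a 7 × 7 window; the second moment gives a spot
radius estimate clamped to [σ~PSF~, 4σ~PSF~].

At the simulated study conditions (SNR ≈ 13 at spot peaks) detection
recall and precision both exceed 0.95 with sub-pixel centroid accuracy;
the acceptance suite verifies this against brute-force bipartite matching
at a 2 px tolerance.

## Axis segmentation and length

Bright curvilinear ridges are enhanced by the smaller Hessian eigenvalue
(Gaussian-derivative kernels at 1.4 σ~PSF~; response −λ₁ clipped at zero),
computed inside a nucleus mask obtained from the chromatin channel
(smooth, Otsu, fill holes, largest component; if no chromatin channel
exists, the axis channel's convex hull is used). Hysteresis thresholding
(high = Otsu of the in-nucleus ridge response; low = 0.4 × high) keeps weak
ridge pixels only when connected to strong evidence. The mask is thinned
to an 8-connected one-pixel skeleton (Guo–Hall), spur branches shorter
than 0.5 µm are pruned, and the skeleton is decomposed into polylines by
walking its adjacency graph (redundant diagonal links removed).

**Length metric.** Length is the summed segment length of the traced
polylines after a light moving-average smoothing of vertex coordinates
(window 5 px, endpoints fixed). The raw 1/√2-weighted chain-step sum is
kept in the result (`chain_length_um`) but is not the headline number: on
smooth curves the raw chain length carries a known positive staircase bias
of up to ~8% at orientations near 22.5°, which the smoothing removes.
With this metric the measured length of intact simulated axes is within
±5% of planted truth, and fragmented axes measure proportionally to the
retained fraction (±10%).

## Overlap scoring and the rotation null

Two per-focus criteria are provided:

* **profile** (default; mirrors the manual line-profile workflow): the
  axis-channel intensity along a horizontal cross-section of half-width
  10 px through the focus centroid is compared to an axis-presence
  threshold (Otsu of the axis channel inside the nucleus); the focus
  overlaps if above-threshold signal occurs within one focus radius of its
  centre. The original procedure does not state a numeric rule for when a
  profile "overlaps", nor the cross-section orientation; one horizontal
  section per focus with an in-nucleus Otsu threshold is this package's
  concrete, orientation-stable choice, and all three ingredients
  (threshold, window, half-width) are parameters.
* **distance**: centroid-to-skeleton distance ≤ `d_max` (default
  2 σ~PSF~). This criterion is exactly characterizable from the masks,
  which makes it the oracle-friendly cross-check; the two criteria agree
  on ≥ 95% of calls in noise-free simulations.

**Rotation null.** Focus positions are point-reflected through the
nucleus-mask centroid rounded to a pixel centre — an exact, interpolation
free 180° rotation on the pixel grid — and re-scored against the
*unrotated* axis; reflections landing outside the nucleus mask are
discarded and reported (`n_random_discarded`), keeping the procedure
auditable. Reflecting about the nucleus centroid rather than the image
centre avoids artefactual misses for off-centre nuclei. For uniformly
placed foci the null fraction matches the axis area fraction (the share of
nucleus pixels within `d_max` of the skeleton) to within ±0.03, and
observed and null fractions are statistically indistinguishable.

**Chance correction.** The estimated fraction of genuinely on-axis foci is
`(observed − chance) / (1 − chance)`. The right `chance` depends on the
placement null for off-axis foci. For real data and for uniform placement
it is the plain axis area fraction (`chance_overlap_fraction()` with
`exclude_um = 0`), estimated in practice by the rotation null. For the
simulator's planted regime — whose off-axis foci deliberately avoid the
2σ~PSF~ neighbourhood of the axis so labels stay unambiguous — the
consistent chance is computed over the same restricted placement region
(`exclude_um = 2 * psf_sigma_um`); with the default `d_max = 2σ` this
chance is ≈ 0 and the correction is nearly the identity. Mixing the two
conventions produces an irreducible bias of `(1 − p)·e/(1 − e)` (e = the
excluded area fraction, ~0.2 under the default axis density), which is why
the package exposes the placement region explicitly instead of hard-coding
one chance definition. With the placement-consistent correction the
planted `p_on_axis` is recovered within ±0.05 across p ∈ {0.2, 0.4, 0.6,
0.8}.

**Degenerate inputs.** Nuclei with zero foci contribute no overlap
fraction (recorded as missing) but contribute density 0; nuclei with zero
axis length contribute no density, and overlapping foci with zero axis
length raise an error (inconsistent input). Foci outside the image raise
an error; foci inside the image but outside the nucleus mask are flagged
and excluded from scoring.

## Group statistics

`mww_test()` is two-sided everywhere, matching the non-directional
significance statements this analysis style reports. For combined sample
sizes ≤ 16 the p-value is exact by full enumeration of all
`choose(n, n_a)` group assignments on midranks — this handles ties
exactly, which the standard exact algorithm does not. Larger samples use
the tie-corrected normal approximation with continuity correction (via
`stats::wilcox.test`); at n = 15 + 15 the approximation stays within 0.01
of the exact p-value and holds its nominal 5% size to within ±1%. The U
statistic follows the `W` convention of `stats::wilcox.test`
(pairs with a > b plus half ties). No multiple-testing correction is
applied: per-comparison p-values mirror how such cytological comparisons
are reported, and downstream correction is the caller's choice.

`percent_change()` and `fold_change()` reproduce the field's display
conventions (integer percent, one-decimal fold).
`first_labelled_times()` tabulates pulse-chase time courses: the earliest
time with a labelled nucleus per stage.

```{r stats-example}
round(percent_change(179, 197))   # leptotene -> zygotene
round(percent_change(179, 211))   # leptotene -> pachytene
mww_test(c(1, 2, 3), c(4, 5, 6))
```

## Numerical choices and problem sizes

* All randomness flows from one integer seed; identical configurations
  are bit-identical end to end (channels are integer counts, stored as
  exact 16-bit TIFF with a YAML sidecar for channel names and pixel size).
* Image containers are plain matrices in counts; EBImage supplies the
  raster primitives (Gaussian filtering, Otsu, labelling, grayscale
  dilation, distance transform); the thinning step is compiled C++.
* Distances from foci to the skeleton are read from a Euclidean distance
  transform at pixel resolution (≤ 0.5 px quantization, ~0.045 µm at the
  default calibration) — small against the 0.26 µm overlap tolerance.
* The validation suite runs the full pipeline at 512 × 512 px (12 µm
  nuclei, ~216 µm of axis, 150 foci), with cohort replicates at
  448 × 448 px and 120 foci, and unit tests at 256 × 256 px with a 7 µm
  nucleus — sizes chosen so the whole suite completes in minutes on one
  core while keeping the axis, PSF and focus-density regime of the
  full-scale default configuration.

## Known limitations

* 2D only; projected z-stacks must be produced upstream.
* The axis length of heavily fragmented nuclei depends on the spur-prune
  length (0.5 µm): stretches shorter than the prune length are discarded,
  so extreme fragmentation is under-measured by design; the retained
  fraction regime tested is 0.5 and above.
* The profile criterion's chance level is not analytically characterized
  (its acceptance region is anisotropic); the distance criterion is the
  calibrated reference, and criterion concordance is verified instead.
* The simulator's mutually avoiding axes mean the pipeline is not
  validated on images where distinct axes genuinely touch or entangle for
  long stretches (e.g. tight synapsis imaged at low resolution).
* Group comparisons assume independent nuclei; no mixed models or nested
  designs.
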