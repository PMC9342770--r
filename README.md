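# meiofoci

Quantitative image analysis for meiotic chromosome-spread
immunofluorescence: focus counting, chromosome-axis segmentation and
length measurement, object-based focus–axis colocalization with a 180°
rotation randomization null, on-axis focus density, and
Mann–Whitney–Wilcoxon group statistics — plus a ground-truthed synthetic
nucleus simulator that makes every stage verifiable.

## Who this is for

Labs that score meiotic recombination cytology: counts of SPO11-1, PRD3,
RAD51 or γH2AX foci per nucleus; the fraction of foci overlapping an
axis stain (ASY1, SMC3, REC8); and focus density per micrometre of axis.
These numbers are usually produced by hand (ImageJ counting, per-section
line profiles). `meiofoci` computes them reproducibly from multi-channel
2D TIFFs, and because no public ground-truth image sets exist for this
assay, it ships a simulator that plants known axes and foci so the
pipeline's accuracy is measurable.

## The quantities at the core

For each nucleus with detected focus set `F`, axis skeleton length `L`
(µm) and per-focus overlap calls:

* overlap fraction `f = |{focus overlaps axis}| / |F|`,
* rotation-null fraction `f₀`: the same score after point-reflecting all
  focus positions through the nucleus centroid (the chance baseline),
* chance-corrected on-axis fraction `p̂ = (f − chance) / (1 − chance)`,
* on-axis density `d = |{overlapping}| / L` (foci/µm).

A focus "overlaps" either when the axis-channel line profile through it
exceeds the in-nucleus Otsu threshold within one focus radius
(`criterion = "profile"`, mirroring the manual workflow) or when its
centroid lies within `d_max = 2σ_PSF` of the axis skeleton
(`criterion = "distance"`, the analytically tractable cross-check).
Group differences are tested two-sided with `mww_test()` — exact by full
enumeration (ties included) for combined n ≤ 16, tie-corrected normal
otherwise.

## Worked example

```r
library(meiofoci)

cfg <- sim_config(image_size_px = c(512L, 512L), n_foci = 150L,
                  p_on_axis = 0.6, seed = 7)
sim <- simulate_nucleus(cfg)        # image stack + ground truth
foci <- detect_foci(sim$image)      # LoG spot detection
seg  <- segment_axis(sim$image)     # ridge -> skeleton -> length
calls <- score_foci(foci, sim$image, seg, coloc_params("distance"))
nul  <- rotation_null(foci, sim$image, seg, coloc_params("distance"))
nucleus_summary(calls, seg, nul)
```

```
nucleus_result: 150 foci, 91 overlapping (fraction 0.607 ; null 0.36 )
  axis 217.14 um; on-axis density 0.419 foci/um
```

The planted truth for this seed had 91 of 150 foci on the axis
(realized fraction 0.607) and 216 µm of axis: the detector found all 150
foci, the overlap calls matched the planted labels exactly, and the
skeleton length is within 1% of truth. The null fraction (0.36)
estimates the chance overlap level given this nucleus's axis density.

A cohort comparison in one call:

```r
res <- run_all(list(
  mode = "simulate", seed = 11,
  simulate = list(groups = list(
    list(name = "axis_enriched", n_nuclei = 10, p_on_axis = 0.7),
    list(name = "axis_depleted", n_nuclei = 10, p_on_axis = 0.4)))),
  out_dir = "cohort_out")
subset(res$comparisons, metric == "overlap_fraction")
```

which writes `coloc_per_focus.csv`, `coloc_per_nucleus.csv`,
`group_comparisons.csv` and a `manifest.yaml` (config echo, seed,
versions, row counts) to `cohort_out/`. A thin command-line wrapper over
the same functions is installed at `inst/scripts/meiofoci.R`
(`simulate`, `detect`, `coloc`, `stats`, `run-all` subcommands).

Staging summaries follow the field's display conventions:

```r
round(percent_change(179, 197))  # +10 (%)  mean foci, leptotene -> zygotene
round(percent_change(179, 211))  # +18 (%)  leptotene -> pachytene
fold_change(0.5, 0.95)           # 1.9 (fold)
```

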