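# tenomac

Spatial and molecular quantification of tendon-resident macrophages.

Tendon fascicles house a sparse population of resident macrophages (GFP⁺
under a *Csf1r* reporter; CD206⁺, F4/80⁺) among the Scx/Col1a1-lineage
fibroblasts. `tenomac` is an R package for the quantification chain used to
characterize them from cryosections, explant cultures, and sorted-cell qPCR:

- **Nuclear segmentation & classification** — global (Otsu) thresholding of
  the Hoechst channel, watershed splitting on the internal distance
  transform, per-nucleus mean intensities, and run-level reporter
  thresholds (`segment_nuclei`, `measure_nuclei`, `classify_by_threshold`).
- **Abundance** — %GFP⁺ and cells/mm² strictly inside the fascicle polygon
  (peritenon excluded), with the Shapiro–Wilk / Levene / one-way ANOVA +
  Tukey battery for group comparisons (`quantify_section`, `compare_groups`).
- **Depth profiling** — a Euclidean distance map from the anterior and
  posterior surface polylines; per-cell normalized depth
  `d = depth / EDM_max`; quartile bins Q1 = [0, 0.25) (outermost) … Q4 =
  [0.75, 1]; enrichment ratios (pct⁺ in quartile) / (pct⁺ whole section),
  equal to 1 under uniform placement (`build_edm`, `assign_depth`,
  `quartile_profile`, `test_uniformity`).
- **Proliferation** — per-animal EdU⁺ fractions within GFP⁺ and GFP⁻
  populations, pooled over sections, compared by paired t-test
  (`edu_fractions`, `compare_proliferation`).
- **Duplex ISH colocalization** — Beer–Lambert colour deconvolution
  (`I_c = I0_c·10^−(MA)_c`) with stain vectors estimated from single-colour
  controls, aggregation on a 50 × 50 µm grid inside the ROI, and Spearman
  rank correlation of the per-unit *Csf1r*/*Csf1* intensities
  (`estimate_stain_vectors`, `deconvolve`, `grid_intensities`,
  `coloc_spearman`).
- **DQ-collagen internalization** — run-level marker thresholds on explant
  cell tables and DQ⁺ percentages within CD206⁺, F4/80⁺, and Col1CFP⁺
  populations (`classify_markers`, `dq_positivity`).
- **qPCR** — duplicate collapse, the undetectable-in-both-populations
  exclusion rule, ΔCT = mean CT(*18s*, *Abl1*, *Rps17*) − CT(gene) (higher =
  more expressed), ΔΔCT = log₂ fold change with exact Mann–Whitney tests,
  unit-variance PCA with marker-oriented PC1 and loading-based gene
  subsetting, hierarchical clustering, and a ligand–receptor crosstalk
  report (`collapse_duplicates`, `apply_exclusions`, `delta_ct`,
  `ddct_contrast`, `pca_and_cluster`, `ligand_receptor_report`).
- **Synthetic data with ground truth** — generators for section images,
  duplex ISH images, explant suspensions, and CT matrices
  (`generate_section`, `generate_duplex_ish`, `generate_suspension`,
  `generate_ct_matrix`), with `preset()`s that encode the measured study
  conditions (e.g. GFP⁺ rising from 1.6% at P4 to 7.9% at P56 in patellar
  tendon; a 2.5× macrophage:fibroblast EdU ratio at P1; 75.4% DQ⁺ within
  CD206⁺ cells).

The staged pipeline (`run_stage("all", config)`; stages `synth`, `segment`,
`abundance`, `depth`, `edu`, `ish`, `qpcr`, `internalize`) writes CSV tables
plus a JSON report of every parameter used, and reruns are byte-identical
given the same config and seed. A thin CLI wrapper lives at
`inst/cli/tenomac.R`.

## Worked example

```r
library(tenomac)

# a synthetic P56 patellar section with known ground truth
spec <- preset("P56-patellar", seed = 1)
gen  <- generate_section(spec)
lab  <- segment_nuclei(gen$image$channels$hoechst, spec$pixel_size_um)
rec  <- measure_nuclei(lab, gen$image$channels, spec$pixel_size_um)
rec  <- classify_by_threshold(rec, "gfp", 60)
quantify_section(rec, spec$fascicle_polygon, section_id = "P56-1")
#>   section_id n_total n_pos pct_pos density_total density_pos density_neg roi_area_mm2
#> 1      P56-1    1542   135   8.755          1469       128.6        1340         1.05

# explant suspension: DQ-collagen positivity by marker population
tab <- classify_markers(generate_suspension(preset("explant-dq", seed = 1)))
dq_positivity(tab)
#>        measure    pct n_denominator
#> 1  dq_in_cd206 74.460          2502
#> 2   dq_in_f480 68.605          2717
#> 3    dq_in_cfp  0.549         12018
#> 4 cd206_in_cfp  0.308         12018
#> 5  f480_in_cfp  1.331         12018
```

The first block reads: 1,542 nuclei were segmented inside the 1.05 mm²
fascicle ROI, 8.8% of them GFP⁺ (this seed's ground truth is 8.7%; the
preset parameter is 7.9%), at a total density of 1,469 cells/mm². The second
block reads: 74.5% of CD206⁺ cells are DQ-collagen⁺ versus 0.5% of Col1CFP⁺
fibroblasts, and CD206⁺CFP⁺ double-positives are rare (0.3% of CFP⁺ cells) —
macrophages, not fibroblasts, internalize degraded collagen.

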