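---
title: "Quantifying tendon-resident macrophages: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tendon-resident macrophages: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Tendon-resident macrophages are a sparse immune population living among the
fibroblasts of the tendon fascicle. Characterizing them from cryosections and
sorted-cell qPCR raises a chain of quantification problems: finding nuclei in
a Hoechst channel and deciding which are reporter-positive; expressing
abundance as percentages and spatial densities inside a manually outlined
fascicle (the macrophage-rich peritenon sheath must be excluded); asking
whether macrophages sit at preferred depths between the anterior and
posterior tendon surfaces; comparing EdU labelling between macrophages and
fibroblasts in neonatal sections; quantifying duplex chromogenic in situ
hybridization for a ligand (*Csf1*) and its receptor (*Csf1r*) on a physical
grid; classifying explant-derived cells by marker intensity and DQ-collagen
uptake; and normalizing a Fluidigm-style CT matrix into interpretable
expression contrasts. `tenomac` implements each stage as a tested, reusable
function, and ships a synthetic-data generator whose presets encode the
measured study conditions so that every stage can be validated by parameter
recovery against known ground truth.

# Image model and segmentation

A section is a calibrated multi-channel raster (`section_image`): Hoechst,
GFP, and optionally EdU, with named ROI polygons (the fascicle) and
polylines (the two tendon surfaces). All exported coordinates are
micrometres, 0-based, y-down; pixel indices never cross a module boundary.

Segmentation follows the standard particle-analysis recipe for such
sections: a global threshold on the Hoechst channel (Otsu on the min-max
normalized image by default, hence invariant to affine intensity rescaling;
a fixed threshold is available), watershed splitting on the internal
Euclidean distance transform, and removal of components outside
[`min_area_um2`, `max_area_um2`] (defaults 8-200 um^2, bracketing the 15-25
um^2 elliptical nuclei the generator renders). Watershed seeds must be at
least 2 um apart (`seed_sep_um`), i.e. half the preset nucleus minor axis,
and the flooding tolerance is 0.3 distance-map units, chosen on dense
synthetic sections so that touching nuclei in linear arrays split reliably
without fragmenting isolated nuclei. Border-touching nuclei are kept and
flagged `on_border`.

Reporter classification is deliberately minimal: `mean intensity >
threshold` with a run-level threshold shared by every image of a comparison
(the packaged presets use 60 of the 8-bit-scaled GFP range and 100 for EdU).
Per-image thresholds would silently re-normalize group contrasts, so the API
only accepts one value per run. Manual counting, used in the original
workflow for EdU and F4/80, is not reproducible in software and is replaced
by thresholded classification throughout.

# Abundance and group comparison

`quantify_section()` counts only nuclei whose centroid falls strictly inside
the fascicle polygon; percentages are `100 * n_pos / n_total`, densities are
counts over the polygon area (um^2 / 1e6). `compare_groups()` reproduces the
statistical battery used for these endpoints: Shapiro-Wilk per group and
Levene's test as preflight checks, then one-way ANOVA with Tukey's post hoc
test at alpha = 0.05. Animals, not sections, are the statistical unit:
sections are averaged (or pooled) within animal before any test, since
sections from one animal are pseudo-replicates. A nonparametric fallback
(Kruskal-Wallis) can be requested but is off by default because the
parametric battery is the reference analysis for these endpoints.

# Depth profiling

`build_edm()` rasterizes the two surface polylines at quarter-pixel steps
and computes an exact Euclidean distance transform, in floating point;
distances are not quantized to a 16-bit integer scale (the integer depth of
the original tooling was an implementation artifact, not a method choice).
Each nucleus receives the mean EDM over its mask; normalized depth is
`d_norm = depth / EDM_max`, with `EDM_max` taken over in-ROI *pixels* (not
over cells — the deepest point of the map is a property of the geometry).
Quartiles are `Q1 = [0, 0.25)` (outermost) through `Q4 = [0.75, 1]` (closed
upper edge). The enrichment ratio reported per quartile is the percentage of
positive cells within the quartile divided by the whole-section percentage,
which equals 1 in every quartile under spatially uniform placement and whose
cell-count-weighted mean is exactly 1 by construction. The alternative
reading — the share of the positive population per quartile over the share
of all cells — is available via `normalization = "population_share"`; the
two coincide under uniformity but differ under mixed composition, and the
within-quartile-percentage reading is the default because it is the one that
normalizes out age differences in overall composition. Sections with
sectioning artifacts are excluded upstream by a manual QC flag; no automated
artifact detector is attempted.

# Duplex ISH colour deconvolution and grid colocalization

Brightfield RGB is modelled by Beer-Lambert attenuation: `I_c = I0_c *
10^-(M A)_c`, with `M` a 3x3 matrix of unit-norm optical-density vectors
(green probe, red probe, nuclear counterstain) and `A` per-pixel stain
amounts. Stain vectors are estimated from single-colour control sections as
the unit-normalized mean OD direction over pixels with OD norm above a small
floor (0.05); optical density uses `clip(I, 1, I0)` to guard the logarithm
on 8-bit-scaled data. The counterstain vector comes from a Hoechst-only
control; if no such control exists it is completed as the normalized cross
product of the two stain vectors. Deconvolution inverts `M`, clips negative
amounts, and snaps amounts below 1e-9 of the maximum to exact zero — without
that snap, floating-point residue at unstained pixels breaks rank ties
arbitrarily and makes the rank correlation depend on numerical noise.
Condition numbers above 50 (near-collinear vectors) are an error.

Deconvolved amounts are averaged on an axis-aligned 50 x 50 um grid anchored
at the ROI bounding-box origin; a unit enters the table only if at least 50%
of its pixels are inside the ROI (the unit-inclusion rule and anchor are the
package's choices; the sensitivity to the anchor can be probed by shifting
the polygon). Colocalization is summarized by Spearman's rank correlation
with tie-corrected ranks (exact p for n <= 10 untied units, asymptotic
otherwise), and sections aggregate as the arithmetic mean of per-section rho
and of per-section p. Only the rank correlation is offered: whether grid
intensities are measured on inverted 8-bit channels or on optical densities
is immaterial for ranks, so the statistic is robust to that unknowable
convention.

# qPCR analysis

Technical duplicates are averaged first (one missing duplicate keeps the
present value with a QC flag; discrepancies above one cycle are flagged).
A panel gene is excluded by rule only when more than one sample in *each* of
the macrophage and fibroblast populations is undetectable (missing or CT at
or above the detection limit, default 40 — a common qPCR convention);
assay-quality exclusions (e.g. abnormal amplification curves) are taken from
an explicit manual list, never auto-detected. Expression is
`dCT = mean(CT of 18s, Abl1, Rps17) - CT(gene)`, so higher values mean higher
expression and the measure is invariant to per-sample plate shifts;
`ddCT = mean dCT(A) - mean dCT(B)` is read directly as log2 fold change.
Group contrasts use the two-sided exact Mann-Whitney U test, with no
multiple-testing gate (a Benjamini-Hochberg column is emitted as
supplementary output only).

PCA treats samples as observations and genes as variables, centred and
scaled to unit variance (Pareto and no-scaling options exist), via singular
value decomposition; per-PC variance percentages sum to 100. Because a PC's
sign is arbitrary, PC1 is oriented so the macrophage marker set (Adgre1,
Cx3cr1, C1qc, Csf1r, Mrc1) has positive mean loading, making the
"macrophage-high" direction deterministic for tests and downstream
subsetting; the macrophage-analysis gene subset is every gene with PC1
loading > 0. Hierarchical clustering uses correlation distance with average
linkage. Pre-amplification of the cDNA is not modelled: CT values are taken
as given, a documented limitation. The ligand-receptor report pairs ligand
expression in the sender population with receptor expression in the receiver
(defaults: Csf1-Csf1r, Il6-Il6ra, Cx3cl1-Cx3cr1 fibroblast-to-macrophage;
Gas6-Axl, Tgfb1-Tgfbr2, Pdgfb-Pdgfra macrophage-to-fibroblast), with
Mann-Whitney age contrasts per gene; missing or excluded pair genes yield
flagged rows, never errors.

# The synthetic-data generator

The generator is first-class, tested code; it defines the conditions under
which the pipeline is validated.

**Sections.** The fascicle is an elongated band with gently undulating
surfaces. Cell count is Poisson(density x area); classes are independent
Bernoulli draws of the macrophage fraction; positions come from an
axis-parallel row lattice with lateral jitter, reproducing the linear-array
texture that makes watershed segmentation non-trivial without modelling
collagen. `depth_bias` biases *macrophage* placement toward the surfaces
(weight `exp(-bias * depth / max depth)`); fibroblasts are always
depth-uniform, so enrichment ratios are 1 in expectation at `depth_bias = 0`
and Q1-skewed otherwise. A peritenon band of macrophage-rich cells surrounds
the fascicle to exercise ROI exclusion. Nuclei are rendered as filled
ellipses with class-conditional Gaussian intensities, EdU at fixed high SNR
(labelled nuclei are bright by construction: EdU detection difficulty is not
the object of study), additive Gaussian noise, and 16-bit quantization as
the acquiring scanner would apply — which also makes the TIFF round trip
bit-exact. All randomness flows from explicit spec seeds through a local
RNG; no global state is consumed.

**Presets.** Measured quantities are fixed: GFP+ fractions 1.6% (P4) and
7.9% (P56) patellar, 1.4%/4.8% Achilles; P1 EdU rates 0.20 vs 0.08
(ratio 2.5); explant DQ rates 75.4% (macrophages) vs 0.5% (fibroblasts) with
0.4% CD206+ and 1.3% F4/80+ among CFP+ cells and a 67.9% DQ rate within the
F4/80+ pool; the qPCR design of 2 populations x 2 tissues x 2 ages x 5
replicates in technical duplicate (80 columns). Where the studies give no
number, values are chosen once as field-realistic and documented: pixel size
0.5 um/px; densities falling from 8000 cells/mm^2 at P1 to 1500 at P56 as
matrix synthesis outpaces proliferation; section bands from 1.2 x 0.25 mm
(P1) to 3.0 x 0.35-0.45 mm (P56); nuclei 8 x 4 um (7 x 3.5 at P1); GFP+/-
intensity models separated by ~10 noise SDs so that classification error is
negligible relative to sampling noise; P14/P28 fractions interpolated
between the measured P4 and P56 values. The explant preset's
negative-population marker spreads are back-computed from the measured
joint percentages at the packaged threshold of 100 (e.g. the fibroblast
CD206 SD is set so that P(intensity > 100) = 0.004).

**ISH.** Expressing cells shed Poisson-many optical-density puncta;
macrophages express the green (receptor) probe, a `csf1_high_fraction`
subset of fibroblasts the red (ligand) probe, all nuclei the counterstain.
`coloc_kappa` is the probability that a macrophage is placed within the
adjacency radius (15 um) of a Csf1-high fibroblast instead of uniformly;
`ish-uniform` (kappa = 0) and `ish-colocalized` (kappa = 0.9) bracket the
uniform null and strong adjacency. The mixing is exactly Beer-Lambert, so
deconvolution with the generating matrix is exact in the noise-free limit
(the closure tests demand <= 1e-6 relative error). Stain amounts are kept
below the OD range where the `clip(I, 1, I0)` guard would activate.

**qPCR.** CT = baseline - offset + noise for panel genes and baseline +
noise for housekeeping genes, so the specified offsets *are* the true dCT
values and noise-free recovery must be exact. Two panel genes are rendered
undetectable in both populations (exercising the exclusion rule) and one is
reserved for the manual exclusion list.

**What the generator does not emulate** — and hence what passing tests do
not demonstrate about real data: optical point-spread and chromatic
aberration, collagen autofluorescence texture, uneven illumination,
sectioning artifacts, nucleus shape irregularity beyond ellipses,
cross-hybridization and probe efficiency differences, and qPCR
pre-amplification bias. Recovery results certify the computational
pipeline, not the acquisition chain.

# Validation scale and numerical choices

The packaged validation runs at desk scale, chosen as the package's own
testing conditions: abundance recovery uses 4 seeds per preset (roughly
6,000-14,000 in-ROI cells per preset); proliferation uses 4 virtual animals
x 10 sections (within the 9-14 sections per sample used for neonatal
counting); depth uniformity uses 20 uniform and 8 surface-biased sections at
a reduced 500 x 200 um geometry; ISH comparisons use 20 seeds per
colocalization condition; explant tables use 20,000 cells x 4 seeds. At
these sizes the Monte-Carlo standard errors are small enough that the
recovery targets are discriminating (e.g. ~0.1 percentage points on the P4
abundance), while a full run of the test suite plus the acceptance script
stays within a desktop coffee break.

Numerical conventions collected in one place: Otsu on 256 bins of the
min-max range; watershed tolerance 0.3, seed separation 2 um; EDM computed
in floating point with quarter-pixel polyline rasterization (agreement with
exact point-to-segment distance is certified to within one pixel); depth
quartile upper edge closed at 1; OD floor 0.05 for stain-vector estimation
and condition-number bound 50; deconvolved amounts below 1e-9 of maximum
snapped to zero; exact Mann-Whitney whenever groups are untied; PCA sign
fixed by marker orientation; detection limit CT 40, duplicate-discrepancy
QC at 1 cycle. Degenerate inputs are contracts, not crashes: blank rasters
segment to zero labels, empty ROIs yield missing percentages, empty marker
denominators yield missing percentages with their size reported, constant
genes are dropped from PCA with a warning, and samples missing a
housekeeping CT lose their dCTs with a warning.

# Known limitations

Threshold classification on overlapping marker distributions implies small,
quantifiable cross-contamination between population pools: with the explant
preset's measured rarity rates, the CD206+ pool is ~98% macrophages, so the
recovered DQ percentage within CD206+ sits ~1.5 points below the macrophage
class rate. This is a property of the measurement design itself (any real
pool has it), and the recovery tests budget for it explicitly. Segmentation
on very dense neonatal sections loses ~1-2% of nuclei to merging even after
watershed tuning; because merging is nearly class-blind, percentage
estimates shift by far less. The ISH model renders puncta as flat disks and
ignores optical blur; absolute rho values are therefore generator-specific,
and only ordering and null behaviour (colocalized > uniform, uniform
centred on zero) are asserted. The pipeline is strictly 2D: depths are
in-plane distances, not geodesic or 3D distances.
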