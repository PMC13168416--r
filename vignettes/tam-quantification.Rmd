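---
title: "Quantifying the spatial TAM landscape of brain metastases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the spatial TAM landscape of brain metastases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Brain metastases (BrM) recruit a mixed tumor-associated macrophage (TAM)
compartment: resident microglia (MG), infiltrating monocyte-derived
macrophages (MDM), and border-associated macrophages (BAM) of the
meninges and choroid plexus (CP). Their relative abundance shifts with
lesion size and brain compartment - MG dominate small parenchymal
microtumors, MDM take over large tumor masses, and border lesions host
BAM instead of MG. `tamscape` implements the quantitative machinery for
measuring those shifts on segmented section images: lesion size
stratification, periphery/interior/intertumoral region decomposition,
reporter-based cell classification, density and ratio metrics, a
flow-cytometry gating hierarchy, and the accompanying statistics.

Because no raw imaging or cytometry data are publicly deposited, the
package ships a first-class synthetic-data module that generates
sections and event tables with known ground truth. Every downstream
stage is validated by recovering the parameters the generator was
programmed with.

## Geometry

**Inputs.** A labeled tumor mask (integer raster, 0 = background, k > 0 =
lesion id), drawn upstream from DAPI staining; segmentation itself is out
of scope. Coordinates are 0-based `(row, col)` with pixel centers at
integer positions. Components are 8-connected.

**Calibration.** The default linear pixel size is 0.5681818 um/px - the
value consistent with a 338,511.7 um2 field imaged at 1024 x 1024 px.
Areas convert in two modes. `linear_squared` (default,
`area = px * 0.5681818^2`) is physically coherent and is used throughout
the simulation/quantification pipeline so programmed intensities and
measured densities share one convention. `legacy_area_factor`
(`area = px * 0.5681818`) reuses the linear size as a per-pixel area
factor; it is the convention behind the published pixel-to-um2 bin-bound
conversions (2000 px -> 1136, 4000 px -> 2272, 6000 px -> 3409 um2 at
printed precision, which truncates) and is kept so those printed numbers
are reproducible. The two conventions cannot be reconciled - nor can the
published pixel bins and um2 bins themselves - so both ship as explicit
presets (`size_bins_preset("methods_px")`, `size_bins_preset("results_um2")`)
and no reconciliation is attempted. One printed bound (10,000 px paired
with 6,818 um2) is arithmetically inconsistent with every other printed
pair, which pin the factor near 0.5681; the package reproduces the
self-consistent values and yields 5,681 um2 for 10,000 px.

**Lesion floor.** Components below 130 um2 are dropped (and logged)
before any region computation, mirroring the DAPI-dense detection floor.

**Periphery band.** The tumor periphery is a 7-px-wide band centered on
the lesion border, extending equally inward and outward. On a raster we
define the border as the lesion's border pixel layer (lesion pixels with
a background 4-neighbor) and take the band to be every pixel within
Euclidean distance 3.5 px (center-to-center) of that layer. This choice
is deliberate: thresholding the distance to the *opposite phase* at 3.5
yields an effectively 6-px band (-12% against the analytic annulus
`pi*(53.5^2 - 46.5^2)` for a 50-px disc), whereas the border-layer
dilation matches the annulus to ~0.3%. The interior is the lesion minus
the inner band; lesions narrower than the band have an empty interior
(warning, not error). Outer-band pixels claimed by several lesions go to
the nearest border, ties to the lower id, so per-lesion densities never
double count. The distance transform is the exact Euclidean EDT
(`EBImage::distmap`), and the test suite checks it against an exhaustive
per-pixel brute force for exact equality.

**Intertumoral region.** Background pixels at >= 4 um (center-to-center,
converted via the linear pixel size) from every lesion pixel. The 4-um
buffer excludes cells potentially touching a border. Between-tumor
densities divide by the *tumor-free area* (frame minus lesions, buffer
**not** subtracted), exactly the published normalization - so that
estimator is deliberately not unbiased for the intertumoral intensity;
the `nontumor` record (intertumoral denominator) is.

**Point distances** (cell-to-lesion, used by the 4-um rules and
touching/non-touching classification) are exact center-to-center
distances from the sub-pixel cell coordinate to the nearest lesion
pixel, 0 inside a lesion.

## Cell classification

Identity comes from lineage reporters, with Iba1 as the master myeloid
gate; phenotype markers (TMEM119, CD68, F4/80) may be carried as
annotation but never drive identity. Four model rules are implemented;
in the Cx3cr1-lineage model the compartment disambiguates tdT+/Iba1+
cells (MG in parenchyma, BAM candidate at borders, where such cells lack
the MG signature). Cells in the open interval between the touching
tolerance (one pixel) and the 4-um non-touching rule are reported
separately as `excluded_buffer` rather than silently merged, because
neither published rule assigns them. Perivascular BAM misread as MG in
the parenchyma cannot be excluded by any reporter combination available
here; no disambiguation is attempted.

## Densities and derived measures

All densities are cells per 0.01 mm2. Whole-tumor denominators are
interior + full band (inner and outer halves). Per-mouse summaries pool
counts over pooled areas (ratio of sums) across a mouse's sections,
which is unbiased under unequal region areas; mean-of-ratios is
available by option. MG/MDM ratios are computed per mouse and a zero MDM
count yields an explicit NA (excluded from ratio statistics with a
warning) rather than an infinity. Proliferation is the Ki-67+ percentage
of reporter+ cells within an arbitrary scope; CD206 co-expression is the
four-way (reporter x CD206) partition of Iba1+ cells.

## Synthetic data

The generator defines the study conditions. A section spec fixes the
frame (1024 x 1024 px, 338,511.7 um2), the tumors, and the programmed
ground truth; cells are a homogeneous Poisson process per (class,
region): expected count = intensity x area / 0.01 mm2, positions uniform
over region pixels with sub-pixel jitter (so region membership holds by
construction), markers set by inverting the active model's
classification rule, Ki-67/CD206 drawn Bernoulli. Ground truth lives in
reserved columns (`true_class`, `true_region`) that the pipeline never
reads, so recovery tests are leak-proof. Determinism: identical spec and
seed give byte-identical outputs.

Default intensities (cells/0.01 mm2) encode the measured trend
structure rather than any exact published value (raw data are not
available to fit): microtumor sections are MG-dominant with a strong
peripheral peak (MG 8/45/12 for nontumor/periphery/interior, MDM
1.5/8/5); major-tumor sections invert the balance (MG 8/25/15, MDM
1.5/20/45), so the MG/MDM ratio is > 1 in microtumors and < 1 in major
tumors. Ki-67 defaults: 25% for tumor-associated MG, 2% nontumor MG, 1%
MDM. CD206 defaults: 75% of BAM candidates, 78% of MDM, 10% of MG - the
border-lesion co-expression levels. The default cohort is 8 mice x 3
sections (two microtumor fields with 3 small/2 medium/2 large lesions,
one major tumor).

One deliberate scaling: the published "major tumor" threshold
(> 338,511.7 um2) equals one full frame, so no in-frame lesion can
exceed it. `assign_size_class` keeps the faithful default, while the
synthetic study uses an operational major threshold of 100,000 um2 so
its near-frame-filling blob (~200,000 um2) is classed "major".

What the generator does **not** emulate: microscopy noise, point-spread
functions, segmentation error, cell morphology (cells are points),
marker misexpression, spatial clustering beyond region-homogeneous
Poisson. Passing recovery tests therefore demonstrates correctness of
the measurement pipeline, not robustness to real-world imaging noise.

## Flow cytometry

Gates are rectangular on raw intensities - no compensation, no
biexponential transform - since the published scheme specifies none;
reproducibility is preferred over realism. Within CD11b+ events the
tdT x GFP quadrants give Q2 (tdT+/GFP+, MDM) and Q3 (tdT-/GFP+, MG);
each is subdivided on CD45 x CD11b into subpopulations i-iii. The lower
CD11b tier for Q3 is annotated "low" in the published median table but
"int" in the gating figure; both labelings are accepted
(`gate_config(q3_cd11b_tier=)`), defaulting to "low". Neutrophils are the
six-marker conjunction CD11b+ CD45+ tdT+ GFP- Ly6C+ Ly6G+. FMI is
`median(signal) - median(FMO)`, negative values reported as-is with a
warning.

Numeric cut values are not published; the defaults are valley midpoints
(geometric means) between the default mixture's population medians. The
synthetic mixture draws each event from a lognormal cluster around
per-population channel medians patterned on the published
lung-carcinoma subpopulation table, with weights 40% Q2 / 55% Q3 / 3%
neutrophils / 2% double-negative and the published within-quadrant
splits. The default log-sd (0.035) keeps every population at least 5
log-sd from the nearest default cut, the well-separated regime in which
fraction recovery to < 1% absolute at 50,000 events is the designed
behavior. FCS parsing is intentionally not implemented; event tables
arrive as CSV.

## Statistics

Responses are variance-stabilized (`sqrt`, signed cube root, or guarded
`log`) before a full-factorial least-squares ANOVA (interactions
included by default; switchable, since the published three-way analyses
do not state whether interactions were fitted). Post-hoc linear
contrasts on cell means use the pooled residual variance - the standard
choice for factorial designs when only "post-hoc linear contrasts" is
specified - with a Welch/Satterthwaite option. Families of p-values are
corrected by the two-stage Benjamini-Krieger-Yekutieli procedure:
stage 1 runs BH at `q' = q/(1+q)` to estimate the null count, stage 2
runs BH at `q' * m/(m - r1)`; decisions at q < 0.05. Family membership
is a configuration input (the published analyses group families per
figure without enumerating them). Spearman correlation uses mid-ranks
with exhaustive-permutation p-values for n <= 8 (tie-valid) and the
t-approximation above; the Mann-Whitney U test uses the exact null
distribution for small samples (closed form when tie-free, enumeration
under ties while feasible) and a tie-corrected normal approximation
otherwise.

Under a 2000-replicate global-null simulation (two one-way layouts of 5
groups x 4, all 20 pairwise contrasts), the realized false-discovery
proportion of the ANOVA-to-FDR chain stays below q = 0.05 (the
acceptance script recomputes this each run).

## Problem sizes and numerical choices

The shipped study conditions are 8 mice x 3 sections of 1024 x 1024 px
(~60,000 cells) and 50,000 flow events; the full test suite and the
acceptance script each complete in a few minutes on one CPU. Recovery
tolerances are 3 SE (Poisson for densities, binomial for fractions) at
the programmed values - chosen a priori from the generator's sampling
distributions, not tuned. Cells exactly on a region boundary follow
mask rasterization (their containing pixel); there is no sub-pixel
adjudication, which keeps counting deterministic. Degenerate inputs are
contracts, not crashes: empty masks give empty lesion lists, zero
denominators give flagged NAs, all-background FMO sets and zero-area
regions are errors.

## Known limitations

* The geometry is strictly 2-D with isotropic pixels; 3-D stacks are out
  of scope.
* The published pixel/um2 bin systems are internally inconsistent; the
  package exposes both verbatim rather than adjudicating.
* Real gating practice uses data-driven gates and compensation; the
  rectangular config-driven gates here trade that realism for exact
  reproducibility.
* Synthetic recovery validates the measurement chain, not segmentation
  or staining variability, which the generator does not model.
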