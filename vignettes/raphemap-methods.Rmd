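---
title: "Mapping transcriptomic neuron subtypes onto binned ISH atlases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping transcriptomic neuron subtypes onto binned ISH atlases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-cell RNA sequencing partitions dorsal-raphe serotonergic (5-HT)
neurons into transcriptomic subtypes, but dissociation destroys anatomy:
the clusters carry no spatial coordinates. `raphemap` reconstructs the
spatial layout of such subtypes indirectly, by correlating each cluster's
averaged expression profile with spatially binned in situ hybridization
(ISH) signal measured gene by gene across coronal sections. The package
also converts registered coordinates of retrogradely labeled
(projection-defined) neurons into probability maps comparable with those
subtype maps, and quantifies per-cell FISH puncta co-expression in gated
cell populations.

## The spatial correlation model

All maps share one voxel geometry (`grid_spec()`): square 50 µm × 50 µm
bins in the coronal plane, 36 × 36 bins per section, 12 sections spaced
100 µm along the anterior-posterior (AP) axis — 15,552 voxels. For every
gene g and voxel v the imaging stage produces a positive-cell count
$x_{gv}$; for every gene and subtype s the single-cell side provides the
cluster-averaged expression $y_{gs}$. After per-gene normalization (below)
the subtype map is the Pearson correlation across the shared genes,

$$ r_{sv} = \frac{\sum_g (y_{gs}-\bar y_s)(x_{gv}-\bar x_v)}
{\sqrt{\sum_g (y_{gs}-\bar y_s)^2}\sqrt{\sum_g (x_{gv}-\bar x_v)^2}}, $$

computed over pairwise-complete genes (at least 3; otherwise `NA`). A
voxel is attributed to the subtype with the largest $r_{sv}$ when a hard
assignment is needed. For display only, maps are thresholded at r > 0.1
and smoothed with a 1-bin Gaussian; quantitative operations never consume
rendered maps.

### Normalization of "expression scores"

The two modalities live on incomparable scales (binned cell counts vs
log-normalized cluster means). The default `normalize = "zscore"`
standardizes each gene row of *both* inputs — the profile across
subtypes, the matrix across voxels — before correlating, so each gene
contributes its spatial and cluster *pattern* rather than its magnitude.
Because no published definition of the normalization exists for this
procedure, a `raw` mode is retained for sensitivity analysis; the
parameter-recovery results reported by the package hold under the
default.

## The imaging stage

Each per-gene, per-section grayscale image passes through:

1. **Block-mean downsampling** (`downsample_image()`, default factor 2).
   Block means preserve total intensity in expectation and introduce no
   interpolation ringing. The factor exists to reduce micron-scale atlas
   scans to a workable resolution; images that are already at working
   resolution (like the synthetic ones, generated at 10 µm/px) are
   processed with factor 1.
2. **Midline estimation** (`estimate_midline()`): the mirror axis
   maximizing $\sum_j I(\cdot,j)\,I(\cdot,2c-j)$ over half-integer axis
   positions, evaluated as anti-diagonal sums of the column Gram matrix.
   Ties break toward the image center. A small Gaussian pre-blur
   (`midline_smooth_px`, default 2 px) stabilizes the score on sparse
   dotty images.
3. **Fixed-width crop** (`align_and_crop()`, default 1 mm) centered on
   the midline, zero-padded outside the image; for even pixel widths the
   extra pixel falls to the right.
4. **Binarization** (`binarize()`): Otsu's histogram threshold by
   default (via EBImage), a per-gene fixed threshold as override. A
   constant image yields an all-`FALSE` mask plus a warning rather than
   an error, so a blank section degrades gracefully.
5. **LoG spot detection** (`detect_spots()`): scale-normalized
   negated-Laplacian-of-Gaussian response at `sigma_um` (default 6 µm),
   strict 8-neighborhood maxima, greedy non-maximum suppression within
   `min_separation_um` (default 12 µm). The detection threshold is
   `max(0.05 · max(response), 14 · mad(response))`. The fractional term
   adapts to overall signal strength; the MAD floor is the essential
   guard on sections where a gene is not expressed — there the maximum of
   the response is itself a noise extremum, and a purely relative
   threshold would convert every such section into ~10² false spots,
   flattening all spatial structure. The floor (14 MAD) sits above the
   measured extreme-value range of the zero-clipped background-noise
   response (≈ 12 MAD on a 180² image) and below the weakest single-cell
   response (≈ 17 MAD at the default blob scale). Detection runs on the
   grayscale image with the binary mask as a gate on peak positions; both
   behaviors are configurable. The detector assumes blob-like cells
   occupying a minority of pixels; heavily crowded fields saturate
   (counts become sub-linear in true cell number) — a physical limit of
   count-based ISH quantification at coarse pixel sizes, not a tunable.
6. **Binning** (`bin_spots()`): half-open, lower-inclusive 50 µm bins
   (a spot exactly on an interior boundary joins the higher-index bin),
   0-based voxel ids, ML increasing rightward and DV downward (image
   convention). Out-of-grid spots are dropped and reported, so counts are
   conserved by construction.
7. **DV fine alignment** (`fine_align_dv()`): integer shift (|offset| ≤ 3
   bins) maximizing the correlation of DV marginal profiles against the
   marker gene's histogram of the same section — an automated stand-in
   for the manual reference-guided adjustment, with a `manual_offset`
   escape hatch. Positive offsets move content toward dorsal. Ties
   prefer the smallest offset magnitude.
8. **Reflection averaging** (`reflect_average()`): $(H + H^{mirror})/2$,
   enforcing exact (bitwise) ML symmetry while preserving the total
   count.
9. **Vectorization** (`section_to_grid_vector()`): concatenation in
   (section, DV row, ML column) order; missing sections travel as `NA`
   blocks and all downstream statistics are missing-aware
   (pairwise-complete Pearson, `NA`-ignoring means and variances).

## Matrix filtering

Voxels are masked by a marker gene expressed across the whole structure
(Tph2 in the real study; configurable): keep voxels with marker count
> 0. Genes are then filtered on total count (default ≥ 20) and on the
Fano factor (sample variance / mean) of their voxel counts. The Fano
default is 0.7: for histograms that have been reflection-averaged, an
unstructured (Poisson) gene sits at Fano ≈ 0.5 — averaging the two
hemispheres halves the variance — so the spatial-variability cutoff is
placed 40% above that baseline. (A cutoff of 1.0, natural for raw Poisson
counts, deletes genuinely informative genes in the low-count-per-voxel
regime.) On the shipped synthetic study this filter retains exactly the
100 subtype-enriched genes and removes the 20 spatially flat background
genes. Whether the total-expression filter runs before or after masking
is a config switch (`filter_before_mask`, default after), since the
statistics are always computed on the matrix the filter sees.

## Density maps and overlap

`density_map()` bins a labeled population with the same conventions and
normalizes by the total in-grid cell count, giving a per-voxel
probability distribution (Σp = 1 ± 1e-9 enforced by construction and
asserted in tests). Pairwise population comparisons are Pearson
correlations of the flattened probability vectors, computed by default
over the marker-masked voxel set (an open choice in the source
procedure; a config switch disables masking). Smoothing is never applied
before correlation. `overlap_fraction()` integrates a population's
probability mass over the voxels where a subtype's correlation exceeds
the display threshold, giving a scalar in [0, 1] that ranks candidate
source subtypes for a projection-defined population. An optional
`mirror_ml` folds bilateral populations onto one hemisphere before
binning (off by default, logged when used).

## FISH positivity and proportions

A cell is positive for a probe at ≥ 3 puncta ("minimum of 3" read
inclusively); the threshold applies uniformly to gate probes (e.g. the
serotonin-transporter and rabies-transcript channels) and subtype probes,
with per-probe overrides available. `coexpression_proportion()` gates
conjunctively, requires at least one gated cell (an empty gate is an
error, deliberately distinct from a true 0% result), and rounds
percentages half-away-from-zero to match whole-number reporting. Given
tables carrying the published RbV-labeled cell counts, the operation
returns exactly the published percentages (52%, 46%, 57%, 4%).

## The synthetic generator

`generate_ground_truth()` plants: per-subtype domains (2D Gaussians per
section, in-plane SD 150 µm, whose centers drift linearly along AP under
a Gaussian AP envelope of 1.5 sections), symmetrized about the ML midline
and normalized to unit mass; and gene loadings with ≥ 4× enrichment
ratios (enriched 5, off-target 0.5, background 1, ±20% uniform jitter).
Domains are made bilateral because the pipeline's reflection averaging
keeps only the symmetric part of any signal — with asymmetric truth the
recovery target would be ill-posed. The default split assigns
`floor(n_genes / (n_subtypes + 1))` enriched genes per subtype, so the
standard study (5 subtypes, 120 genes) is 20 enriched per subtype plus
20 shared background genes.

`simulate_ish_image()` draws Poisson cell counts with mean
`cells_per_unit` × (loading-weighted domain mass in the section), places
cells uniformly within voxels, renders 6 µm Gaussian blobs at 10 µm/px,
adds Gaussian noise (SD 0.05) and clips to [0, 1]. The default
`cells_per_unit = 400` yields a few hundred positive cells per section
for a strongly expressed gene — typical of chromogenic ISH — while
keeping nearest-neighbor distances mostly above the resolvability limit
of 10 µm pixels. The generator emulates dot-like expression over smooth
domains; it deliberately omits tissue texture, Nissl background, optical
PSFs and droplet-level count noise, so passing tests demonstrate the
pipeline's correctness on its stated model, not robustness to every
artifact of real atlas imagery.

Cluster profiles are the loadings under multiplicative lognormal noise
of unit mean and selectable CV (`noise_cv`, study default 0.1);
projection cells are sampled from weighted domain mixtures; FISH puncta
are Poisson(20) for enriched probe-subtype pairs and Poisson(0.2)
otherwise, making the ≥ 3 threshold's error rates closed-form
(`1 - ppois(2, 0.2)` ≈ 0.11% false positives, `ppois(2, 20)` ≈ 4e-6
false negatives). Every generator takes one integer seed and touches no
global RNG state.

## Validation and problem sizes

The test suite validates each operation against independent oracles
(explicit-formula Pearson vs the pairwise-complete reference, exhaustive
midline and DV-offset scans, within-class-variance scans for Otsu,
planted spot positions, Poisson tail probabilities) and runs the full
study end to end: 5 subtypes × 120 genes × 12 sections at 10 µm/px
(1,440 images, ≈ 90 s on one core), where argmax-subtype assignment is
required to be correct in ≥ 90% of voxels inside the planted domains'
half-maximum supports (the shipped study scores 100% at profile noise
CV 0.1). Spot detection must reach F1 ≥ 0.95 against planted centroids
on noise-free sections with ≥ 4σ separation. Unit tests use a reduced
12 × 12 × 3 grid, where the cramped field makes domains overlap; its
recovery check is a sanity bound (> 0.6), not the headline criterion.

## Known limitations

- Counts saturate where cells merge at the working pixel size; the
  correlation analysis tolerates compression but absolute counts are not
  calibrated densities.
- Midline estimation assumes approximately bilateral signal; a section
  imaged far off-center with strongly unilateral expression can misplace
  the axis by a few pixels.
- The AP axis is nearest-section assignment (ties anterior), not
  continuous registration; no interpolation between sections.
- The Fano cutoff presumes reflection-averaged count histograms; users
  feeding unaveraged matrices should raise it toward the Poisson
  baseline of 1.
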