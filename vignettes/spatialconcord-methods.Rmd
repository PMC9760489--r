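---
title: "Methods: quality control and cross-modality concordance for imaging-based spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality control and cross-modality concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialconcord)
```

## The problem

Multiplexed-FISH platforms (MERFISH and kin) read single RNA molecules in
tissue by decoding combinatorial binary barcodes over rounds of imaging.
The decoded output is a table of transcripts with micron coordinates, a set
of 2D cell-boundary polygons from segmentation, and a nuclear (DAPI) stain
raster. Before any biology can be read off, three downstream problems must
be solved reproducibly:

1. **Transcript-to-cell assignment.** Segmentation is 2D at the median
   z-slice of the stack (the 4th plane of 7, spaced 0.7 µm). The package
   projects each boundary through the whole volume — the "cookie cutter" —
   so a transcript at any z belongs to the cell whose median-z polygon
   contains its (x, y).
2. **Cell-level quality control.** Segmentation quality is variable; some
   boundaries are drawn over empty space. Cells are kept when their area,
   total counts, and *average DAPI score* (mean nuclear intensity over
   pixels inside the boundary) are plausible.
3. **Concordance with sequencing.** Whether the imaging modality's counts
   behave like scRNA-seq counts is settled with a battery of statistics:
   replicate and pseudo-bulk correlations, per-cell dropout rates, per-gene
   detection fractions, nonzero-cell means, the mean–variance relation, and
   negative-binomial fits; plus a spatial co-occurrence ratio and a
   cross-modality cosine-similarity diagnostic.

Because real imaging runs are terabyte-scale, the package ships a synthetic
tissue generator with complete ground truth, so every stage is testable
end-to-end with exact answers.

## Coordinate and boundary conventions

One convention is used everywhere: coordinates in µm, origin at the mosaic
top-left, x rightward, y downward, z-plane indices 0-based. A raster pixel
in row *i*, column *j* (1-based in R) has its centre at
((j − ½), (i − ½)) · `pixel_size`. Points on a polygon boundary count as
*inside* (edge molecules are not lost, and the rule is deterministic).
Where segmentation polygons overlap, a transcript goes to the
smallest-area containing polygon, ties broken by lexicographic cell id —
deterministic and favouring the more specific segment. DAPI averaging uses
pixel-centre membership rather than area weighting: it is unambiguous and
directly checkable against explicit enumeration.

## Quality control

Defaults follow the standard cutoffs for this kind of data: cell areas in
[200, 3000] µm², at least 80 transcripts per cell, and an average DAPI
score of at least 400 camera units. All thresholds are inclusive on the
keep side (the natural reading of a "minimum cutoff"). The QC report
tallies each criterion independently — a cell failing two criteria
increments both counters — because the non-exclusive tally is more
informative and does not change the retained set.

The average-DAPI distribution of a mixed population is bimodal: real cells
score near nuclear intensity, empty-space segments near background.
`suggest_dapi_threshold()` offers an advisory Otsu threshold (256-bin
between-class-variance maximiser). When the two modes are cleanly
separated the Otsu objective is flat across the empty gap; the function
returns the middle of the plateau rather than its first bin, so the
suggestion lands mid-gap. `apply_qc()` always uses the explicit configured
threshold, never the suggestion.

One terminological wrinkle: the score is described in places as a "median
average DAPI"; the package implements the mean-within-polygon score, the
definition the metric's histograms are built from.

Sample-level RNA integrity (RIN) is laboratory metadata, not computed from
data; the pipeline excludes samples with RIN < 4 up front and records the
exclusion in the run manifest.

## Count statistics

- **Dropout rate** (per cell): fraction of the whole gene panel with zero
  counts. Computed against the full panel size, not the matrix columns, so
  imaging and sequencing datasets restricted to the same panel are
  directly comparable.
- **Detection fraction** (per gene): fraction of cells with nonzero
  counts. The two satisfy an exact duality — total nonzero entries counted
  per row equals the total counted per column — which the tests assert.
- **Nonzero-cell means**: plain means over cells with nonzero counts, with
  SEM = sample SD (n − 1) / √n, reported only for genes with at least 50
  nonzero cells in the dataset. No truncated-likelihood correction is
  applied — the plain conditional mean is the quantity of interest; the
  test suite checks it against the numerically computed zero-truncated NB
  expectation.
- **Bulk correlations**: Pearson on log10(1 + x) per-gene totals over the
  shared gene set. The log base is a documented choice (correlation is
  insensitive to base); Pearson-on-log is the conventional flavour for
  bulk scatter comparisons.
- **Normalization for clustering**: scale each cell to 10,000 total
  counts, ln(1 + x), then centre and scale each gene to zero mean and unit
  variance using the population SD, without clipping. Genes with zero
  variance map to zero columns.

### Negative-binomial fitting

Counts are modelled as NB(µ, r) with variance µ + µ²/r (Poisson limit
r → ∞). The MLE of µ given r is the sample mean for this parameterisation,
so the fit profiles the likelihood over log r with a Brent search
initialised at the method-of-moments estimate r₀ = m²/(s² − m), with a
relative tolerance of 1e-12 on the profile objective (tighter than the
1e-8 contract). Samples whose variance does not exceed their mean sit on
the Poisson boundary of the family; the fit flags them `poisson_limit` and
reports the documented sentinel r = 1e8 rather than a divergent estimate.

A genuine limitation: when µ ≪ r the NB is nearly Poisson and the Fisher
information for r vanishes. At µ = 0.5, r = 10 the dispersion MLE has a
relative SD of roughly 0.4 even at n = 10,000 — no estimator resolves r to
20% there, and any cross-library comparison shows the same spread. The
test suite exercises dispersion recovery in the identifiable regime and
documents this corner.

## Spatial co-occurrence

For an ordered label pair (i, j) and distance band (d_lo, d_hi], the
co-occurrence ratio is R(d) = P(i | j, d) / P(i, d): the fraction of
label-i cells among all band neighbours of label-j anchors, relative to
the same fraction pooled over all anchors. R = 1 under spatial
independence; R > 1 means enrichment of type i near type j.

The estimator is defined explicitly as *pooled band counts*, not an
average of per-anchor ratios — the two differ when anchor neighbour counts
vary, and the pooled form is the plain conditional-probability estimator,
exactly checkable against brute-force pair counting (the tests require
bit-for-bit agreement with an exhaustive per-anchor oracle). Distances are
Euclidean on centroids, bands half-open (lo, hi], a cell is never its own
neighbour, and default bins are 25 linear bands to 1,000 µm. Bands with no
neighbours are reported as undefined (NA), never zero-filled.

Note that label permutation on a fixed label vector is sampling without
replacement, which gives R a small O(1/n) bias away from 1 (cross-label
pairs slightly enriched); the null-calibration check is therefore stated
as "mean within 3 SD of 1" across trials.

## Cross-modality similarity

For each query cell and reference label, the diagnostic is the mean over
reference cells of that label of cos(q, r) = q·r/(‖q‖‖r‖) on a chosen gene
subset. Cosine similarity is invariant to per-cell scaling, so raw counts
are the default input — total-count differences between modalities do not
affect it, and no normalization choice needs defending. Cells expressing
none of the selected genes (zero norm) contribute similarity 0 by
convention, with a warning count, avoiding NaN propagation. Named marker
presets ship for the two worked cases (podocyte; periportal hepatocyte).
The annotation confusion matrix is row-normalized over the sorted union
vocabulary; rows whose manual label has no cells are emitted as NA, not
zeros.

## The synthetic tissue generator

`generate_tissue()` emulates the statistical structure the analysis
assumes, with full ground truth:

- **Geometry.** Cells are random convex polygons inscribed in jittered
  30 µm grid slots (radius 0.38–0.48 × pitch, jittered regular vertex
  angles), which makes them simple, convex, and non-overlapping by
  construction without a tessellation dependency. Areas land near
  400–550 µm², inside the QC window.
- **Layout.** Alternating 150 µm bands along x carry different cell-type
  mixtures; the first two panel types (and their partner types 3 and 4)
  dominate alternate bands, emulating periportal/pericentral zonation and
  giving the co-occurrence statistic a real signal to find.
- **Expression.** Per-type NB(µ, r) counts from the panel model: 10 marker
  genes per type at mean ~20 counts/cell (log-normal jitter), baseline 0.3
  for other tissue genes, dispersion r = 3. Pancreas-class genes are
  knocked down to near zero — an off-tissue false-positive control.
- **Extracellular RNA.** Each molecule is relocated to empty space with
  probability 0.30, reproducing the ~70% assignable fraction typical of
  tissue runs.
- **Bad segments.** 5% of polygons are planted on empty background: no
  nucleus beneath, no transcripts sourced. Their average DAPI lands at
  background (~100), far below the 400 cutoff.
- **Crowding.** Molecule-wise thinning with detection probability
  p(T) = 1/(1 + T/saturation), saturation 1,000 counts/cell: a smooth,
  monotone, concave saturation that reproduces the divergence of detected
  counts in high-expressing cells. The functional form is a modelling
  choice (the mechanism — loss of single-molecule resolvability — fixes
  the shape only qualitatively).
- **DAPI raster.** Gaussian nucleus blobs (σ = 4 µm, amplitude
  ~30,000 ± 3,000) at good-cell centroids over Gaussian background
  (100 ± 20), 16-bit clipped, 1 µm/px.
- **Matched scRNA-seq.** Same NB model, then entry-wise zeroing with
  probability 0.5. The value implements the defining contrast between the
  modalities — a dissociative droplet modality captures several-fold fewer
  molecules than imaging — at its conservative end: after the tissue
  modality pays its own losses (30% extracellular, crowding thinning), the
  sequencing modality still ends up with visibly higher per-cell dropout
  and lower per-gene detection, which is the pattern the concordance
  statistics are designed to expose.
- **Seeding.** All randomness flows from one integer seed through a
  counter-based splitting scheme (`split_seed()`), so sub-generators
  (layout, shapes, counts, thinning, placement, DAPI noise) are
  independently reproducible and insensitive to how much randomness the
  others consume.

What the generator does *not* emulate: optical spot decoding and its error
correction, segmentation errors other than the planted empty-space
segments (no merged or split cells), cell-shape diversity (no concave or
elongated cells), 3D structure (counts are placed uniformly across
z-planes), doublets, ambient-RNA contamination in the sequencing modality,
and batch effects. Passing tests therefore demonstrate correctness of the
computations under the stated generative model, not robustness to every
artefact of real tissue runs.

## Barcode codebooks

`generate_codebook()` builds constant-weight codebooks (default weight 4,
minimum pairwise Hamming distance 4 — the standard error-robust scheme;
constant-weight words always differ by an even distance). Construction is
seeded random-order greedy over all constant-weight words with up to 32
restarts, keeping the largest packing; capacity is reported, not
guaranteed, and a shortfall raises a distinct warning class rather than an
error. Panel candidate filtering removes genes with fewer than 30 probe
target regions or bulk abundance above 800 FPKM, boundary values retained
(strict inequalities define removal).

## Pipeline and formats

`run_pipeline()` executes simulate → assign → qc → concordance →
crossmodal → spatial from a single YAML configuration and seed, writing
each intermediate in an open format — transcripts CSV (17-significant-digit
coordinates for exact double round-trips), segmentation GeoJSON (closed
rings, `cell_id` property), 16-bit single-channel TIFF for DAPI, Matrix
Market coordinate-integer triplets with barcode/feature sidecars, label
CSVs and JSON reports — and records every file with an MD5 checksum in a
manifest. Re-runs with the same configuration and seed are bit-identical;
stages whose recorded outputs still match their checksums are skipped.
Configuration validation reports every problem at once.

## Problem sizes used by the test suite

The suite validates at deliberately desk-sized conditions: tissue fields
of 300 × 240 to 900 × 600 µm (60–450 cells, ~10⁴–10⁵ transcripts),
scRNA-seq draws of 2,000–10,000 cells, 50-instance oracle sweeps with up
to 500 cells for the spatial statistic, and 50 permutation trials at
n = 2,000 for the null calibration. These sizes give the statistical
assertions comfortable margins while keeping the full suite around a
minute of compute.
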