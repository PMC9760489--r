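# spatialconcord

Quality control and cross-modality concordance analysis for imaging-based
spatial transcriptomics.

Imaging platforms such as MERFISH decode single RNA molecules in tissue,
yielding a transcript table (gene, x, y, z in µm), 2D cell-segmentation
polygons at the median z-slice, and a DAPI nuclear-stain raster. This
package implements the downstream pipeline that turns those into
trustworthy single-cell count matrices and then asks, quantitatively, how
the imaging modality compares with single-cell RNA sequencing:

- **Transcript-to-cell assignment** by the "cookie cutter" rule: each
  cell's median-z boundary is projected through the whole z-stack, and a
  transcript at any z is assigned to the cell whose polygon contains its
  (x, y).
- **Image-anchored QC**: cells are kept when their area lies in
  [200, 3000] µm², total counts ≥ 80, and the *average DAPI score* (mean
  nuclear intensity over pixels inside the boundary) ≥ 400 — the score
  that flags segments drawn over empty space.
- **Concordance statistics**: replicate/pseudo-bulk Pearson correlations
  on log10(1 + x) totals; per-cell dropout rates (fraction of the panel
  with zero counts); per-gene detection fractions; nonzero-cell means with
  SEM; the mean–variance relation; and maximum-likelihood fits of the
  negative binomial NB(µ, r) with Var = µ + µ²/r.
- **Spatial co-occurrence**: the ratio R(d) = P(i | j, d) / P(i, d) over
  distance bands — 1 under spatial independence, > 1 where cell type *i*
  is enriched near type *j* (the periportal/pericentral zonation readout).
- **Cross-modality similarity**: per query cell, the mean cosine
  similarity against reference cells of each label, on the full panel or
  marker subsets, plus row-normalized annotation confusion matrices and
  composition tables.
- **A synthetic tissue generator** with complete ground truth — zonated
  NB expression, ~30% extracellular transcripts, planted empty-space
  segments, optical-crowding saturation, a matched higher-dropout
  scRNA-seq modality — so every stage is validated against exact answers.

It is aimed at people building or auditing analysis pipelines for
imaging-based spatial data who need each step to be small, explicit, and
testable.

## Worked example

```r
library(spatialconcord)

panel  <- synthetic_panel(seed = 1)              # 307-gene, 10-type panel
cfg    <- synthetic_tissue_config(seed = 2)      # 900 x 600 um, 450 cells
tissue <- generate_tissue(panel, cfg)

tx <- assign_transcripts(tissue$transcripts, tissue$segmentation)
assignable_fraction(tx)
#> [1] 0.7040454

ct <- build_cell_table(tx, tissue$segmentation, tissue$dapi,
                       genes = panel$genes)
qc <- apply_qc(ct$cells, qc_config())
qc$report
#> qc_report: 450 of 472 cells retained (yield 95%)
#>   failed area: 0, counts: 22, DAPI: 22 (non-exclusive)
```

About 70% of transcripts fall inside a segmented boundary (the rest are
extracellular), and QC removes exactly the 22 planted empty-space segments
— their average DAPI sits at background, far below the 400 cutoff.

```r
counts <- ct$counts[qc$cells$cell_id, ]
top <- top_abundant_genes(counts, 1)
fit_negative_binomial(counts[counts[, top] > 0, top])
#> nb_fit: mu = 13.73, size r = 1.169 (n = 184, logLik = -671.60)

sc <- generate_scrna(panel, 2000, seed = 3)      # matched sequencing run
median(dropout_rates(counts, 307))    # imaging:    0.8566775
median(dropout_rates(sc$counts, 307)) # sequencing: 0.8892508

log_correlation(bulk_gene_totals(counts), bulk_gene_totals(sc$counts))$r
#> [1] 0.9619186
```

The abundant marker gene is overdispersed (r ≈ 1.2, so variance far above
the Poisson line), the imaging modality shows the lower per-cell dropout,
and the two modalities agree well at the bulk level — the qualitative
pattern the concordance battery is designed to expose.

The full pipeline, driven by one config and seed with checksummed,
bit-reproducible outputs:

```r
manifest <- run_pipeline(run_config(out_dir = "run1", seed = 7))
```

A thin CLI wrapper for the same stages ships in
`inst/scripts/spatialconcord`.

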