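# hmtiquant

Automated single-cell quantification for highly multiplexed tissue imaging
(HMTI): from per-channel grayscale TIFF tiles to a flow-cytometry-compatible
`[cells × parameters]` matrix.

Iterative stain–image–bleach platforms (ChipCytometry-style, CyCIF, and
related) export one background-subtracted grayscale image per marker per
position. Quantifying them per cell is hard for two reasons this package
addresses head-on:

1. **Tissue compartments segment differently.** Densely packed, dimmer
   epithelial nuclei and bright immune nuclei defeat any single
   threshold/filter combination. hmtiquant segments epithelial and
   non-epithelial cells separately by subtracting segmented crypts
   (Yen-thresholded pan-cytokeratin regions ≥ 1000 px): non-epithelial cells
   first (size 70–400 px, circularity ≥ 0.55) on the crypt-masked nuclei
   image, then epithelial cells (75–2000 px, circularity ≥ 0.2) on the
   residual — recovering roughly 1.5× as many cells as a single pass on
   crypt-containing tissue.

2. **Neighbours contaminate signals.** In dense tissue a cell's measured
   surface signal often belongs to an adjacent cell or an antibody
   aggregate. After pre-processing (conditional-median outlier filter +
   minimum filter), **spatial spillover correction (SSC)** subdivides each
   cell ROI into four quadrants at its centroid and deletes a marker signal
   whose largest quadrant holds more than 60% of the cell's total signal
   (evaluated only on cells with mean intensity > 100); deleted ROIs are
   archived for inspection. For a cell ROI *R* with centroid-split quadrants
   *Q₁..Q₄* and channel intensity *I*:

   delete if max_q [ Σ_{p∈Q_q} I(p) / Σ_{p∈R} I(p) ] > 0.60

Everything downstream of segmentation — per-cell mean intensities, x/y
centroids, area, circularity, QC (≥ 3 expressed markers, size cap), FCS 3.1
and CSV export, SNR evaluation, and replotting of gated populations onto
tissue coordinates — is included, as is a synthetic tissue generator with
full ground truth (crypts, clustered immune infiltrates, mutually exclusive
marker pairs, spillover aggregates, speckles) that makes the entire pipeline
testable without any external data.

## Worked example

Generate the built-in synthetic dataset (an 896×896 px position with ~640
cells, rendered to 2×2 TIFF tiles for an 11-marker immune panel) and run the
full pipeline:

```r
library(hmtiquant)

demo <- make_demo(seed = 1, out_dir = "demo")
res  <- run_all(demo$config)

res$segmentation
#> <label_map> 896x896, 637 cells (220 epithelial, 417 non-epithelial)

res$ssc$CD4
#> <ssc_result> CD4: 177 retained, 27 deleted, 433 skipped (gate 100, threshold 0.6)

tab <- res$table
head(as.data.frame(tab)[, c("cell_id", "compartment", "x", "y", "area_px",
                            "circularity", "mean_CD4", "mean_CD8")], 3)
#>   cell_id    compartment     x      y area_px circularity mean_CD4 mean_CD8
#> 1       1 non_epithelial 659.4  74.64     217      0.7868 428.4700   0.7281
#> 2       2 non_epithelial 307.8 815.41     232      0.7599   0.8664   1.4655
#> 3       3 non_epithelial 334.5  35.95     229      0.7115   1.1834   0.0000
```

637 of the 642 true cells are segmented (the 2×2 grid of tiles is stitched
with per-pixel-maximum fusion first). On the CD4 channel, 27 cells carried
signal concentrated enough in one quadrant to be deleted as spillover; 433
were below the 100-intensity gate. Gating the exported table like flow
cytometry data:

```r
sum(tab$mean_CD4 > 100 & tab$mean_CD8 > 100)   # exclusive-pair double positives
#> 2        (0.31% of cells; 7.8% without SSC)

tregs <- tab$cell_id[tab$mean_CD45 > 100 & tab$mean_CD3 > 100 &
                     tab$mean_CD4 > 100 & tab$mean_Foxp3 > 100]
length(tregs)                                   # rare Treg-like population
#> 23
overlay <- replot_gate(tab, tregs, res$rois)    # footprints back on the tissue
```

`mean_CD4 = 0` with `ssc_deleted_CD4 = 1` marks an SSC deletion (cell 3
above). `res$paths$fcs` is an FCS 3.1 file readable by flow-cytometry
software; `read_fcs()` round-trips it to float32 precision. A run log
(`run_log.json`) records every parameter of the run.

A thin command-line front end with `demo`, `run-all`, `stitch`, `segment`,
`preprocess`, `ssc` and `quantify` subcommands is installed at
`inst/scripts/hmtiq`.

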