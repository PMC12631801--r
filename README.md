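# orgsig — organelle signature analysis of 3D multi-channel cell images

Different cell types devote very different shares of their volume to their
organelles, and remodel organelle shape, contacts and placement under
stress. `orgsig` turns per-cell 3D label images of six organelles —
endoplasmic reticulum (ER), Golgi (GL), lipid droplets (LD), lysosomes
(LS), mitochondria (MT) and peroxisomes (PO) — plus cell and nucleus masks
into a per-cell **organelle signature**: a curated vector of 234 metrics of
organelle morphology, pairwise interaction, and subcellular distribution,
together with the statistical screen used to compare cell populations. It
is written for quantitative cell biologists and image analysts who already
have segmentations (from any segmentation tool) and want a reproducible,
tested measurement and screening layer. A seeded synthetic-cell phantom
generator with known ground truth makes every stage testable without
microscopy data.

## What is computed

* **Instancing.** Binary masks become instance labels under 26-connectivity:
  voxels touching by face, edge or corner — i.e. structures within one
  voxel's distance — are one object. ER, cell and nucleus are constrained to
  a single object per cell.
* **Morphology** (per object, physical units): volume, triangulated-isosurface
  surface area, SA:volume ratio, equivalent diameter
  `d_eq = (6V/π)^(1/3)`, extent, cubical-complex Euler number, solidity,
  moments-based major axis length; summarised per cell as count, total
  volume, volume fraction, median object volume, SD of object volumes, and
  the median of each shape metric.
* **Interactions.** For each of the 15 organelle pairs, interaction sites
  are the connected regions of voxel overlap; per cell: site count,
  total/median/SD of site volumes, and the percentage of each parent
  organelle's objects involved.
* **Distribution.** Five concentric XY rings interpolated between the
  nucleus edge (ring 1, which contains the nucleus) and the cell edge via
  the normalized radial coordinate `d = D_nuc / (D_nuc + D_edge)`, eight
  45° wedges per ring, and ten Z bins from the bottom to the top of the
  cell. Object volume per region is normalized as
  `n(r) = (raw(r)/total) / (region cell volume(r)/cell volume)`, so a
  uniformly distributed object has `n(r) = 1` everywhere; summaries are the
  mode and positional SD of `n(r)` and the median over rings of the wedge
  coefficient of variation.
* **Signature.** The full per-cell panel (~600 columns) and the curated
  234-metric signature: 65 morphology + 60 interaction + 109 distribution
  metrics in a fixed documented column order.
* **Screen.** Per-metric two-sided Mann-Whitney U tests between groups with
  the two-stage Benjamini-Krieger-Yekutieli linear step-up procedure at
  FDR 10% (tiers `*`..`****` at q ≤ 0.1/0.05/0.01/0.001), mean rank
  differences and log2 fold changes; standardized PCA with
  parallel-analysis component retention (1000 simulations, 95th
  percentile); Ward ("ward.D") hierarchical clustering on Euclidean
  distances; Spearman correlation matrices.
* **Dynamics.** Particle-track summaries from 2D time-lapse point tables
  (5 s frame interval): displacement, total distance, rolling 10-frame
  median speed, SD of speed, and tortuosity.

## Worked example

```r
library(orgsig)

# one synthetic astrocyte-like cell with known ground truth
res <- simulate_cells("astrocyte_like", 42)[[1]]
q   <- quantify_cell(res$image)
round(q$row[c("LS_count", "LS_total_volume", "LS_XY_mode",
              "LS-PO_site_count", "MT_count", "cell_volume")], 4)
#>         LS_count  LS_total_volume       LS_XY_mode LS-PO_site_count
#>          38.0000           8.8376           1.0000          13.0000
#>         MT_count      cell_volume
#>          36.0000         625.6036
```

This cell carries 38 lysosomes totalling 8.8 μm³ with their XY mode in
ring 1 (perinuclear clustering), 13 LS–PO interaction sites, and 36
mitochondria, inside a 626 μm³ cell. Screening two small phantom groups:

```r
res <- run_pipeline(n_per_group = 6, seed = 7, n_sim_pca = 200)
s   <- res$screen
sum(s$significant)                      # 55 of 187 testable metrics
s[s$metric %in% c("MT_count", "LS_total_volume", "LS-PO_site_count"),
  c("metric", "U", "p", "q_value", "tier", "log2_fc")]
#>              metric  U       p q_value tier log2_fc
#>     LS_total_volume  0 0.00216  0.0162   **  -1.997
#>            MT_count 36 0.00492  0.0198   **   0.959
#>    LS-PO_site_count  1 0.00726  0.0275   **  -1.000
res$pca$n_retained                      # 1 component retained
```

The neuron-like group has more mitochondria (positive log2 FC of
`MT_count`), the astrocyte-like group more lysosomal volume and more LS–PO
contacts, and parallel analysis retains one component whose scores separate
the groups.

A command-line front end over the same functions is installed at
`inst/scripts/orgsig.R` with subcommands `simulate`, `quantify`,
`signature`, `screen` and `tracks`, reading and writing TIFF/CSV artifacts.

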