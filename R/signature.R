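# Assembly of per-cell metric rows: the full panel and the curated
# 234-metric organelle signature (65 morphology + 60 interaction +
# 109 distribution metrics).

MORPH_METRICS <- c("volume_fraction", "total_volume", "count",
                   "median_volume", "SD_volume",
                   "median_SA_to_volume_ratio", "median_equivalent_diameter",
                   "median_extent", "median_euler_number", "median_solidity",
                   "median_axis_major_length")
SITE_METRICS <- c("site_count", "site_total_volume", "site_median_volume",
                  "site_SD_volume")
DIST_METRICS <- c("XY_mode", "XY_SD", "XY_median_CV", "Z_mode", "Z_SD")

#' Curated organelle-signature metric names
#'
#' The documented enumeration of the 234 curated metrics: a morphology block
#' (11 amount/size/shape metrics per organelle, minus the ER object count,
#' which is constant 1 because the ER is constrained to a single object
#' during segmentation: 65 columns), an interaction block (count, total,
#' median and SD of site volumes for each of the 15 pairs: 60 columns), and
#' a distribution block (XY mode/SD/median wedge CV and Z mode/SD for the 6
#' organelles and 15 pairs, plus XY and Z mode/SD for the nucleus:
#' 109 columns).
#'
#' @param block one of "all", "morphology", "interaction", "distribution".
#' @return Character vector of metric names in the fixed column order.
#' @export
curated_metric_names <- function(block = c("all", "morphology", "interaction",
                                           "distribution")) {
  block <- match.arg(block)
  morph <- unlist(lapply(ORGANELLES, function(org) {
    m <- MORPH_METRICS
    if (org == "ER") m <- setdiff(m, "count")
    paste0(org, "_", m)
  }))
  inter <- unlist(lapply(ORGANELLE_PAIRS, function(p) paste0(p, "_", SITE_METRICS)))
  dist <- c(unlist(lapply(c(ORGANELLES, ORGANELLE_PAIRS),
                          function(o) paste0(o, "_", DIST_METRICS))),
            paste0("nuc_", c("XY_mode", "XY_SD", "Z_mode", "Z_SD")))
  switch(block,
         morphology = morph,
         interaction = inter,
         distribution = dist,
         all = c(morph, inter, dist))
}

#' Assemble one full-panel row from the stage outputs
#'
#' Concatenates cell/nucleus morphology, per-organelle summaries, interaction
#' summaries (including percent-involved metrics) and distribution summaries
#' (including per-region normalized volumes) into one named numeric vector.
#' Inputs must come from the same cell image.
#'
#' @param scaffold_metrics from [measure_scaffold()].
#' @param organelle_summaries named numeric vector (concatenated
#'   [summarize_organelle()] outputs).
#' @param interaction_summary named numeric vector from [all_pairs()].
#' @param distribution_summary named numeric vector of distribution metrics.
#' @return Named numeric vector (one full-panel row).
#' @export
assemble_cell <- function(scaffold_metrics, organelle_summaries,
                          interaction_summary, distribution_summary) {
  row <- c(scaffold_metrics, organelle_summaries, interaction_summary,
           distribution_summary)
  if (anyDuplicated(names(row))) {
    stop("duplicate metric names in assembled row: ",
         names(row)[duplicated(names(row))][1], call. = FALSE)
  }
  row
}

#' Quantify one cell image into a full-panel metric row
#'
#' Runs the whole per-cell pipeline: instances each organelle channel (ER as
#' a single object), measures cell/nucleus and per-object morphology, all 15
#' pairwise interaction sites, and XY ring / Z bin distribution profiles for
#' every organelle, interaction site, and the nucleus.
#'
#' @param img a validated [cell_image()].
#' @param n_rings,n_wedges,n_bins region counts (defaults 5, 8, 10).
#' @param smooth_sigma surface-area smoothing, see [surface_area3d()].
#' @param keep_records logical; also return per-object morphology records.
#' @return A list: `row` (named full-panel vector) and, when requested,
#'   `records` (per-channel data.frames of object records).
#' @export
quantify_cell <- function(img, n_rings = 5, n_wedges = 8, n_bins = 10,
                          smooth_sigma = 0.85, keep_records = FALSE) {
  img <- validate_cell_image(img)
  sc <- img$scaffold
  cell_vol <- mask_volume(sc$cell)
  scaffold_metrics <- measure_scaffold(sc, intensity = img$intensity,
                                       smooth_sigma = smooth_sigma)
  stacks <- lapply(ORGANELLES, function(n) {
    if (is.null(img$organelles[[n]])) {
      stop("missing organelle channel(s): ", n, call. = FALSE)
    }
    instance_channel(img$organelles[[n]], n)
  })
  names(stacks) <- ORGANELLES
  records <- list()
  org_sum <- list()
  for (org in ORGANELLES) {
    rec <- measure_objects(stacks[[org]], intensity = img$intensity[org],
                           smooth_sigma = smooth_sigma)
    records[[org]] <- rec
    org_sum[[org]] <- summarize_organelle(rec, cell_vol, name = org)
  }
  pairs <- all_pairs(img, smooth_sigma = smooth_sigma, keep_sites = TRUE)
  xy <- build_xy_regions(sc, n_rings = n_rings, n_wedges = n_wedges)
  zr <- build_z_regions(sc, n_bins = n_bins)
  dist_sum <- list()
  prof_one <- function(grid_obj, name, cv = TRUE) {
    px <- profile_regions(grid_obj, xy, name = name)
    pz <- profile_regions(grid_obj, zr, name = name)
    sx <- summarize_distribution(px, cv = cv)
    szm <- summarize_distribution(pz, cv = FALSE)
    out <- c(setNames(sx, paste0(name, "_XY_", names(sx))),
             setNames(szm, paste0(name, "_Z_", names(szm))),
             setNames(px$n, paste0(name, "_XY_n", seq_along(px$n))),
             setNames(pz$n, paste0(name, "_Z_n", seq_along(pz$n))))
    names(out) <- sub("_XY_median_CV$", "_XY_median_CV", names(out))
    out
  }
  for (org in ORGANELLES) {
    dist_sum[[org]] <- prof_one(stacks[[org]], org)
  }
  for (p in ORGANELLE_PAIRS) {
    dist_sum[[p]] <- prof_one(pairs$sites[[p]]$sites, p)
  }
  dist_sum[["nuc"]] <- prof_one(sc$nucleus, "nuc", cv = FALSE)
  row <- assemble_cell(scaffold_metrics, unlist(unname(org_sum)),
                       pairs$summary, unlist(unname(dist_sum)))
  if (keep_records) list(row = row, records = records) else list(row = row)
}

#' Extract the curated 234-metric signature
#'
#' Selects the curated columns (see [curated_metric_names()]) from a
#' full-panel row or table; errors if a required column is absent.
#'
#' @param x named numeric vector (one full-panel row) or a data.frame with
#'   full-panel columns.
#' @return Object of the same shape restricted to the 234 curated metrics,
#'   in the fixed curated order.
#' @export
curate_signature <- function(x) {
  want <- curated_metric_names()
  have <- if (is.data.frame(x)) names(x) else names(x)
  missing_cols <- setdiff(want, have)
  if (length(missing_cols) > 0) {
    stop("full panel is missing required column(s): ",
         paste(head(missing_cols, 3), collapse = ", "), call. = FALSE)
  }
  if (is.data.frame(x)) {
    id_cols <- intersect(c("cell_id", "group", "replicate"), names(x))
    out <- x[, c(id_cols, want), drop = FALSE]
    attr(out, "panel") <- "curated"
    out
  } else {
    x[want]
  }
}

#' Combine per-cell rows into a signature table
#'
#' @param rows list of named numeric full-panel (or curated) rows with
#'   identical names.
#' @param group character/factor group label per row.
#' @param cell_id optional cell identifiers (default seq).
#' @param replicate optional replicate identifiers (kept for batch-effect
#'   inspection).
#' @return A data.frame with columns cell_id, group, replicate, then the
#'   metric columns in row order; row order is stable.
#' @export
batch_combine <- function(rows, group, cell_id = NULL, replicate = NULL) {
  stopifnot(length(rows) >= 1, length(group) == length(rows))
  ref <- names(rows[[1]])
  for (i in seq_along(rows)) {
    if (!identical(names(rows[[i]]), ref)) {
      bad <- c(setdiff(names(rows[[i]]), ref), setdiff(ref, names(rows[[i]])),
               ref[which(names(rows[[i]]) != ref)])
      stop("column mismatch across rows at row ", i, ": first mismatch '",
           bad[1], "'", call. = FALSE)
    }
  }
  if (is.null(cell_id)) cell_id <- paste0("cell_", seq_along(rows))
  if (is.null(replicate)) replicate <- rep("r1", length(rows))
  mat <- do.call(rbind, rows)
  out <- data.frame(cell_id = as.character(cell_id),
                    group = as.character(group),
                    replicate = as.character(replicate),
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(mat, check.names = FALSE))
  rownames(out) <- NULL
  attr(out, "panel") <- "full"
  out
}

# metric columns of a signature table (everything but the id columns)
metric_columns <- function(table) {
  setdiff(names(table), c("cell_id", "group", "replicate"))
}
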