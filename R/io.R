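# File I/O: multi-channel TIFF stacks for cell images, CSV for tables and
# tracks, and the end-to-end pipeline runner behind the command-line script.

CHANNEL_ORDER <- c("cell", "nucleus", ORGANELLES)

#' Write a cell image as a multi-page TIFF
#'
#' Pages are written channel-major in the fixed order cell, nucleus, ER, GL,
#' LD, LS, MT, PO (all Z planes of a channel together), as 16-bit integer
#' label/mask values.
#'
#' @param img a validated [cell_image()].
#' @param path output file path (.tif).
#' @return `path`, invisibly.
#' @export
write_cell_image <- function(img, path) {
  img <- validate_cell_image(img)
  grids <- c(list(cell = img$scaffold$cell$grid * 1L,
                  nucleus = img$scaffold$nucleus$grid * 1L),
             lapply(img$organelles, function(ch) {
               if (inherits(ch, "label_stack")) ch$grid else ch$grid * 1L
             }))
  pages <- list()
  for (nm in CHANNEL_ORDER) {
    g <- grids[[nm]]
    if (is.null(g)) g <- array(0L, dim(img$scaffold$cell$grid))
    if (max(g) > 65535) stop("labels exceed 16-bit range", call. = FALSE)
    for (z in seq_len(dim(g)[1])) {
      pages[[length(pages) + 1]] <- g[z, , ] / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16, reduce = FALSE)
  invisible(path)
}

#' Read a cell image from a multi-page TIFF
#'
#' @param path TIFF written by [write_cell_image()] (or any channel-major
#'   multi-page 16-bit stack).
#' @param spacing voxel spacing (sz, sy, sx) in micrometres.
#' @param channels channel names in page order; must contain "cell",
#'   "nucleus" and the six organelles.
#' @return A validated [cell_image()]; binary organelle channels come back
#'   as semantic masks, integer-labeled ones as label stacks.
#' @export
read_cell_image <- function(path, spacing = c(0.41, 0.16, 0.16),
                            channels = CHANNEL_ORDER) {
  required <- c("cell", "nucleus", ORGANELLES)
  missing_ch <- setdiff(required, channels)
  if (length(missing_ch) > 0) {
    stop("channel map is missing: ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) %% length(channels) != 0) {
    stop("page count ", length(pages), " is not a multiple of ",
         length(channels), " channels", call. = FALSE)
  }
  nz <- length(pages) %/% length(channels)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  sp <- as_spacing(spacing)
  get_channel <- function(i) {
    a <- array(0, c(nz, ny, nx))
    for (z in seq_len(nz)) a[z, , ] <- pages[[(i - 1) * nz + z]]
    if (any(a != floor(a))) {
      stop("non-integer labels in channel '", channels[i], "'", call. = FALSE)
    }
    a
  }
  chans <- lapply(seq_along(channels), get_channel)
  names(chans) <- channels
  org <- lapply(ORGANELLES, function(nm) {
    a <- chans[[nm]]
    if (all(a %in% c(0, 1))) semantic_mask(a > 0, sp) else
      label_stack(array(as.integer(a), dim(a)), sp, channel = nm)
  })
  names(org) <- ORGANELLES
  cell_image(cell_scaffold(semantic_mask(chans$cell > 0, sp),
                           semantic_mask(chans$nucleus > 0, sp)),
             organelles = org)
}

#' Write a ground-truth record as CSV
#'
#' One row per placed object: organelle, object id, volume and centroid,
#' plus the per-pair planted-overlap counts appended as comment-free rows
#' with organelle = "overlap:A->B".
#'
#' @param truth a `ground_truth` from [generate_cell()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  rows <- list()
  for (org in names(truth$organelles)) {
    t0 <- truth$organelles[[org]]
    if (t0$count > 0) {
      rows[[org]] <- data.frame(
        organelle = org, object = seq_len(t0$count), volume = t0$volumes,
        centroid_z = t0$centroids[, 1], centroid_y = t0$centroids[, 2],
        centroid_x = t0$centroids[, 3], stringsAsFactors = FALSE)
    } else {
      rows[[org]] <- data.frame(organelle = org, object = 0L, volume = 0,
                                centroid_z = NA_real_, centroid_y = NA_real_,
                                centroid_x = NA_real_)
    }
  }
  for (ov in names(truth$overlaps)) {
    o <- truth$overlaps[[ov]]
    rows[[paste0("ov_", ov)]] <- data.frame(
      organelle = paste0("overlap:", ov), object = o$planted,
      volume = o$rate, centroid_z = o$n_objects, centroid_y = NA_real_,
      centroid_x = NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a track table from CSV
#'
#' Expects columns track_id, frame, x, y (coordinates in micrometres).
#'
#' @param path CSV path.
#' @param interval_s frame interval in seconds (default 5).
#' @return List of per-track data.frames, frames sorted, with the interval
#'   attached.
#' @export
read_tracks <- function(path, interval_s = 5) {
  tab <- read.csv(path)
  need <- c("track_id", "frame", "x", "y")
  if (!all(need %in% names(tab))) {
    stop("track table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(tab, tab$track_id), function(t) {
    t <- t[order(t$frame), need]
    rownames(t) <- NULL
    attr(t, "interval_s") <- interval_s
    t
  })
}

#' Write a track list as CSV
#'
#' @param tracks list of track data.frames.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  write.csv(do.call(rbind, tracks), path, row.names = FALSE)
  invisible(path)
}

#' Write a signature (or any metric) table as CSV
#'
#' Comma-separated, UTF-8, "." decimal, missing values as empty fields, so
#' re-reading with [read_signature()] round-trips the values.
#'
#' @param table data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(table, path) {
  out <- table
  for (cn in names(out)) {
    if (is.double(out[[cn]])) {
      v <- sprintf("%.17g", out[[cn]])   # round-trips doubles exactly
      v[is.na(out[[cn]])] <- NA
      out[[cn]] <- v
    }
  }
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a signature table written by [write_signature()]
#'
#' @param path CSV path.
#' @return data.frame with metric names preserved verbatim.
#' @export
read_signature <- function(path) {
  tab <- read.csv(path, check.names = FALSE, na.strings = "")
  for (cn in names(tab)) {
    if (is.integer(tab[[cn]]) || is.logical(tab[[cn]])) {
      tab[[cn]] <- as.double(tab[[cn]])
    }
  }
  tab
}

#' Run the end-to-end phantom screen
#'
#' Simulates `n_per_group` cells per preset, quantifies each into the full
#' metric panel, assembles the full and curated signature tables, screens
#' the curated metrics between the two groups (Mann-Whitney U + BKY FDR),
#' and runs parallel-analysis PCA and Ward clustering on the curated table.
#'
#' @param n_per_group cells per preset (default 20).
#' @param seed base seed; per-cell seeds are `seed_base + 1..n` for the
#'   neuron-like group and `seed_base + 500 + 1..n` for the astrocyte-like
#'   group, with `seed_base = seed * 10000`.
#' @param fdr screen FDR (default 0.10).
#' @param n_sim_pca parallel-analysis simulations (default 1000).
#' @param outdir optional directory; when given, writes the tables
#'   (full_panel.csv, signature.csv, screen.csv, pca_scores.csv,
#'   ground_truth per cell) there.
#' @param progress print per-cell progress to stderr.
#' @return List: `full`, `curated` (tables), `screen`, `screen_full`,
#'   `pca`, `hclust`, `truths`.
#' @export
run_pipeline <- function(n_per_group = 20, seed = 1, fdr = 0.10,
                         n_sim_pca = 1000, outdir = NULL, progress = FALSE) {
  base <- seed * 10000
  groups <- list(neuron_like = base + seq_len(n_per_group),
                 astrocyte_like = base + 500 + seq_len(n_per_group))
  rows <- list()
  labels <- character(0)
  reps <- character(0)
  truths <- list()
  for (g in names(groups)) {
    for (s in groups[[g]]) {
      if (progress) message("simulating + quantifying ", g, " seed ", s)
      cellres <- simulate_cells(g, s)[[1]]
      q <- quantify_cell(cellres$image)
      cid <- paste0(g, "_", s)
      rows[[cid]] <- q$row
      labels <- c(labels, g)
      reps <- c(reps, paste0("r", (s %% 4) + 1))
      truths[[cid]] <- cellres$truth
    }
  }
  full <- batch_combine(rows, labels, cell_id = names(rows), replicate = reps)
  curated <- curate_signature(full)
  scr <- mwu_screen(curated, "neuron_like", "astrocyte_like", fdr = fdr)
  scr_full <- mwu_screen(full, "neuron_like", "astrocyte_like", fdr = fdr)
  pca <- pca_parallel(curated, n_sim = n_sim_pca, seed = seed)
  hc <- hier_cluster(curated)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_signature(full, file.path(outdir, "full_panel.csv"))
    write_signature(curated, file.path(outdir, "signature.csv"))
    write_signature(as.data.frame(scr), file.path(outdir, "screen.csv"))
    writeLines(curated_metric_names(), file.path(outdir, "signature_columns.txt"))
    sc <- data.frame(cell_id = curated$cell_id[pca$rows],
                     group = curated$group[pca$rows], pca$scores,
                     check.names = FALSE)
    write_signature(sc, file.path(outdir, "pca_scores.csv"))
  }
  list(full = full, curated = curated, screen = scr, screen_full = scr_full,
       pca = pca, hclust = hc, truths = truths)
}
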