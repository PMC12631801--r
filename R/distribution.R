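# Subcellular distribution profiling: organelle volume across five concentric
# XY rings interpolated between the nucleus edge and the cell edge (ring 1
# innermost, containing the nucleus and the volume above/below it), eight
# angular wedges per ring, and ten contiguous Z bins spanning the cell.

#' Build concentric XY ring and wedge regions from a cell scaffold
#'
#' The cell footprint is the any-voxel projection of the cell mask. Pixels in
#' the nucleus footprint get ring 1; every other footprint pixel is assigned
#' the normalized radial coordinate d = D_nuc / (D_nuc + D_edge) (Euclidean
#' distances to the nucleus footprint and to the background outside the cell
#' footprint) and binned into `n_rings` equal intervals, so rings follow the
#' nucleus and cell shapes like CellProfiler-style proportional rings. Wedges
#' are equal angular sectors about the nucleus centroid, half-open, starting
#' at the +x axis.
#'
#' @param scaffold a [cell_scaffold()]; XY spacing must be isotropic.
#' @param n_rings,n_wedges region counts (defaults 5 and 8).
#' @return An object of class `xy_regions`: ring and wedge maps (Y x X
#'   integer matrices, 0 outside the footprint), per-ring and per-ring-wedge
#'   cell volume, and the cell volume.
#' @export
build_xy_regions <- function(scaffold, n_rings = 5, n_wedges = 8) {
  stopifnot(inherits(scaffold, "cell_scaffold"), n_rings >= 1, n_wedges >= 1)
  sp <- unclass(scaffold$spacing)
  if (abs(sp[["sy"]] - sp[["sx"]]) > 1e-9 * sp[["sx"]]) {
    stop("ring geometry requires isotropic XY spacing (sy == sx)", call. = FALSE)
  }
  cg <- scaffold$cell$grid
  col_counts <- colSums(cg, dims = 1)        # (Y, X) cell voxels per column
  fp <- col_counts > 0
  nfp <- colSums(scaffold$nucleus$grid, dims = 1) > 0
  if (!any(nfp)) stop("nucleus footprint is empty", call. = FALSE)
  d_nuc <- pmax(as.matrix(EBImage::distmap(1 - nfp)) - 1, 0)
  d_edge <- pmax(as.matrix(EBImage::distmap(fp * 1)) - 1, 0)
  tot <- d_nuc + d_edge
  d <- ifelse(tot > 0, d_nuc / tot, 1)
  ring <- matrix(0L, nrow(d), ncol(d))
  ring[fp] <- pmin(pmax(ceiling(d[fp] * n_rings), 1L), n_rings)
  ring[nfp] <- 1L
  # wedges about the nucleus centroid, 0 rad along +x, half-open sectors
  ni <- which(nfp, arr.ind = TRUE)
  cyx <- colMeans(ni)
  yy <- matrix(seq_len(nrow(d)), nrow(d), ncol(d))
  xx <- matrix(seq_len(ncol(d)), nrow(d), ncol(d), byrow = TRUE)
  theta <- atan2(yy - cyx[1], xx - cyx[2]) %% (2 * pi)
  wedge <- matrix(0L, nrow(d), ncol(d))
  wedge[fp] <- pmin(floor(theta[fp] / (2 * pi / n_wedges)), n_wedges - 1) + 1L
  vv <- voxel_volume(scaffold$spacing)
  ring_volume <- vapply(seq_len(n_rings),
                        function(r) sum(col_counts[ring == r]) * vv, 0)
  rw_volume <- matrix(0, n_rings, n_wedges)
  for (r in seq_len(n_rings)) for (w in seq_len(n_wedges)) {
    rw_volume[r, w] <- sum(col_counts[ring == r & wedge == w]) * vv
  }
  structure(list(ring = ring, wedge = wedge, ring_volume = ring_volume,
                 rw_volume = rw_volume, cell_volume = sum(col_counts) * vv,
                 n_rings = n_rings, n_wedges = n_wedges,
                 spacing = scaffold$spacing),
            class = "xy_regions")
}

#' Build Z bins from a cell scaffold
#'
#' The plane range from the lowest to the highest Z plane containing cell
#' mask is partitioned into `n_bins` contiguous bins (bin 1 at the bottom)
#' whose sizes differ by at most one plane; when there are remainder planes
#' they go to the bottom bins, and with fewer planes than bins the excess
#' bins stay empty (volume 0).
#'
#' @param scaffold a [cell_scaffold()].
#' @param n_bins number of Z bins (default 10).
#' @return An object of class `z_regions`: per-plane bin assignment (0 for
#'   planes outside the cell range), per-bin cell volume, cell volume.
#' @export
build_z_regions <- function(scaffold, n_bins = 10) {
  stopifnot(inherits(scaffold, "cell_scaffold"), n_bins >= 1)
  cg <- scaffold$cell$grid
  plane_counts <- rowSums(cg, dims = 1)
  present <- which(plane_counts > 0)
  z0 <- min(present); z1 <- max(present)
  n_planes <- z1 - z0 + 1
  base <- n_planes %/% n_bins
  rem <- n_planes %% n_bins
  sizes <- base + as.integer(seq_len(n_bins) <= rem)
  bins <- integer(dim(cg)[1])
  bins[z0:z1] <- rep(seq_len(n_bins), times = sizes)
  vv <- voxel_volume(scaffold$spacing)
  bin_volume <- vapply(seq_len(n_bins),
                       function(b) sum(plane_counts[bins == b]) * vv, 0)
  structure(list(bins = bins, bin_volume = bin_volume,
                 cell_volume = sum(plane_counts) * vv, n_bins = n_bins,
                 spacing = scaffold$spacing),
            class = "z_regions")
}

#' Regional volume profile of an object
#'
#' Measures the object's raw volume per region (all Z planes for XY rings)
#' and the normalized volume n(r) = (raw(r)/total) / (region cell volume(r) /
#' cell volume), a density enrichment that equals 1 in every region for an
#' object occupying the cell uniformly. For XY regions the per-ring wedge
#' profile is measured the same way.
#'
#' @param object a `semantic_mask`, `label_stack` or logical array (the
#'   object's foreground, assumed inside the cell mask).
#' @param regions an `xy_regions` or `z_regions` object.
#' @param name object name stored on the profile.
#' @return An object of class `region_profile`: `raw` and `n` per region,
#'   `total`, `empty` flag, axis tag, and for XY the wedge matrices.
#' @export
profile_regions <- function(object, regions, name = NA_character_) {
  grid <- mask_grid(object)
  vv <- voxel_volume(regions$spacing)
  if (inherits(regions, "xy_regions")) {
    ocol <- colSums(grid, dims = 1)
    raw <- vapply(seq_len(regions$n_rings),
                  function(r) sum(ocol[regions$ring == r]) * vv, 0)
    total <- sum(raw)
    share <- regions$ring_volume / regions$cell_volume
    n <- if (total > 0) ifelse(share > 0, (raw / total) / share, 0) else
      rep(NA_real_, regions$n_rings)
    wedge_raw <- matrix(0, regions$n_rings, regions$n_wedges)
    for (r in seq_len(regions$n_rings)) for (w in seq_len(regions$n_wedges)) {
      wedge_raw[r, w] <- sum(ocol[regions$ring == r & regions$wedge == w]) * vv
    }
    wshare <- regions$rw_volume / regions$cell_volume
    wedge_n <- if (total > 0) {
      ifelse(wshare > 0, (wedge_raw / total) / wshare, NA_real_)
    } else matrix(NA_real_, regions$n_rings, regions$n_wedges)
    structure(list(name = name, axis = "XY", raw = raw, n = n, total = total,
                   empty = total == 0, wedge_raw = wedge_raw,
                   wedge_n = wedge_n, region_share = share),
              class = "region_profile")
  } else if (inherits(regions, "z_regions")) {
    oplane <- rowSums(grid, dims = 1)
    raw <- vapply(seq_len(regions$n_bins),
                  function(b) sum(oplane[regions$bins == b]) * vv, 0)
    total <- sum(raw)
    share <- regions$bin_volume / regions$cell_volume
    n <- if (total > 0) ifelse(share > 0, (raw / total) / share, 0) else
      rep(NA_real_, regions$n_bins)
    structure(list(name = name, axis = "Z", raw = raw, n = n, total = total,
                   empty = total == 0, region_share = share),
              class = "region_profile")
  } else {
    stop("regions must be xy_regions or z_regions", call. = FALSE)
  }
}

#' Summarise a regional distribution profile
#'
#' Mode = index of the region with the largest normalized volume (ties go to
#' the innermost/lowest region); SD = volume-weighted standard deviation of
#' the region index with weights n(r)/sum n(r), i.e. the positional spread of
#' the object across regions. For XY profiles the per-ring coefficient of
#' variation of the eight normalized wedge volumes is computed (sample SD /
#' mean, as a ratio) and summarised as the median over rings with non-zero
#' object volume.
#'
#' @param profile a `region_profile` from [profile_regions()].
#' @param cv logical; compute the wedge CV summary (XY profiles only).
#' @return Named numeric vector: `mode`, `SD`, and for XY with `cv = TRUE`
#'   also `median_CV`. All missing for an empty profile.
#' @export
summarize_distribution <- function(profile, cv = (profile$axis == "XY")) {
  stopifnot(inherits(profile, "region_profile"))
  k <- length(profile$n)
  if (profile$empty) {
    out <- c(mode = NA_real_, SD = NA_real_)
    if (cv && profile$axis == "XY") out <- c(out, median_CV = NA_real_)
    return(out)
  }
  n <- profile$n
  mode <- which.max(n)  # which.max takes the first (smallest) index on ties
  w <- n / sum(n)
  idx <- seq_len(k)
  mu <- sum(w * idx)
  SD <- sqrt(sum(w * (idx - mu)^2))
  out <- c(mode = as.numeric(mode), SD = SD)
  if (cv && profile$axis == "XY") {
    cvs <- rep(NA_real_, k)
    for (r in idx) {
      if (profile$raw[r] <= 0) next
      nw <- profile$wedge_n[r, ]
      nw <- nw[!is.na(nw)]
      if (length(nw) >= 2 && mean(nw) > 0) cvs[r] <- sd(nw) / mean(nw)
    }
    out <- c(out, median_CV = if (all(is.na(cvs))) NA_real_ else
      median(cvs, na.rm = TRUE))
  }
  out
}
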