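# Pairwise organelle interaction sites: connected regions of voxel overlap
# between two organelle channels, a proxy for membrane contact sites
# (10-80 nm) and areas of close proximity (< 1 voxel in Z, here < 410 nm);
# no distance-resolved classification is attempted beyond voxel overlap.

#' Find interaction sites between two organelle channels
#'
#' The overlap is computed on the semantic foreground of the two channels
#' (union of their instances), then instanced under 26-connectivity like any
#' other channel; each site records the parent instances it touches on both
#' sides. A site spanning several touching parents is kept as one site with
#' multiple parents.
#'
#' @param A,B [label_stack()] objects sharing shape and spacing.
#' @return A list of class `interaction_sites` with fields `pair`, `sites`
#'   (a [label_stack()] of overlap regions) and `parents` (per site, the A
#'   and B instance ids).
#' @export
find_sites <- function(A, B) {
  stopifnot(inherits(A, "label_stack"), inherits(B, "label_stack"))
  if (!identical(dim(A$grid), dim(B$grid))) {
    stop("shape-mismatch between interaction channels", call. = FALSE)
  }
  pair <- paste0(A$channel, "-", B$channel)
  ov <- A$grid > 0L & B$grid > 0L
  sites <- label_instances(semantic_mask(ov, A$spacing), channel = pair)
  parents <- list()
  if (sites$n_labels > 0) {
    idx <- which(sites$grid > 0L)
    sl <- sites$grid[idx]
    al <- A$grid[idx]
    bl <- B$grid[idx]
    parents <- lapply(seq_len(sites$n_labels), function(s) {
      sel <- sl == s
      list(A = sort(unique(al[sel])), B = sort(unique(bl[sel])))
    })
  }
  structure(list(pair = pair, sites = sites, parents = parents,
                 A_channel = A$channel, B_channel = B$channel),
            class = "interaction_sites")
}

#' Summarise an interaction between two channels
#'
#' Site count, total/median/SD of site volumes (SD missing below two sites),
#' and the percentage of A (and of B) instances involved in at least one
#' site; percentages are missing when the corresponding channel is empty.
#'
#' @param sites result of [find_sites()].
#' @param A,B the [label_stack()] objects the sites were computed from.
#' @param smooth_sigma passed to [measure_objects()] for site morphology.
#' @param records logical; also return the per-site morphology records.
#' @return A named numeric vector `<pair>_site_*` (plus `percent_involved`
#'   fields); with `records = TRUE`, a list with fields `summary`, `records`.
#' @export
summarize_interaction <- function(sites, A, B, smooth_sigma = 0.85,
                                  records = FALSE) {
  stopifnot(inherits(sites, "interaction_sites"))
  pair <- sites$pair
  rec <- measure_objects(sites$sites, smooth_sigma = smooth_sigma)
  n <- nrow(rec)
  nA <- A$n_labels
  nB <- B$n_labels
  invA <- length(unique(unlist(lapply(sites$parents, `[[`, "A"))))
  invB <- length(unique(unlist(lapply(sites$parents, `[[`, "B"))))
  out <- c(
    site_count = n,
    site_total_volume = if (n > 0) sum(rec$volume) else 0,
    site_median_volume = if (n > 0) median(rec$volume) else NA_real_,
    site_SD_volume = if (n >= 2) sd(rec$volume) else NA_real_
  )
  out <- setNames(out, paste0(pair, "_", names(out)))
  pct <- c(if (nA > 0) 100 * invA / nA else NA_real_,
           if (nB > 0) 100 * invB / nB else NA_real_)
  names(pct) <- paste0(pair, "_percent_", c(sites$A_channel, sites$B_channel),
                       "_involved")
  out <- c(out, pct)
  if (records) list(summary = out, records = rec) else out
}

#' All 15 pairwise organelle interactions of a cell image
#'
#' Computes interaction sites and summaries for every pairwise combination of
#' the six organelle channels, in the fixed order of [ORGANELLE_PAIRS].
#'
#' @param img a validated [cell_image()] with all six organelle channels.
#' @param smooth_sigma passed to site morphology.
#' @param keep_sites logical; also return the site [label_stack()]s (needed
#'   for distribution profiling).
#' @return A list with `summary` (named numeric vector over all pairs) and,
#'   if requested, `sites` (named list of `interaction_sites`).
#' @export
all_pairs <- function(img, smooth_sigma = 0.85, keep_sites = FALSE) {
  stopifnot(inherits(img, "cell_image"))
  missing_ch <- setdiff(ORGANELLES, names(img$organelles))
  if (length(missing_ch) > 0) {
    stop("missing organelle channel(s): ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  stacks <- lapply(ORGANELLES, function(n) instance_channel(img$organelles[[n]], n))
  names(stacks) <- ORGANELLES
  summaries <- list()
  site_list <- list()
  for (pair in ORGANELLE_PAIRS) {
    ab <- strsplit(pair, "-", fixed = TRUE)[[1]]
    s <- find_sites(stacks[[ab[1]]], stacks[[ab[2]]])
    summaries[[pair]] <- summarize_interaction(s, stacks[[ab[1]]],
                                               stacks[[ab[2]]],
                                               smooth_sigma = smooth_sigma)
    if (keep_sites) site_list[[pair]] <- s
  }
  out <- list(summary = unlist(unname(summaries)))
  if (keep_sites) out$sites <- site_list
  out
}
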