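#' @useDynLib orgsig, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median sd prcomp quantile rnorm runif hclust dist
#'   wilcox.test cor.test rbeta setNames
#' @importFrom utils write.csv read.csv head combn
NULL

#' Canonical organelle channel names
#'
#' The six organelle channels measured by the pipeline, in the fixed order
#' used for all signature columns: endoplasmic reticulum (ER), Golgi (GL),
#' lipid droplets (LD), lysosomes (LS), mitochondria (MT), peroxisomes (PO).
#'
#' @export
ORGANELLES <- c("ER", "GL", "LD", "LS", "MT", "PO")

#' Fixed order of the 15 pairwise organelle interactions
#'
#' Lexicographic pair names ("A-B" with A < B) over [ORGANELLES]; this order
#' is used everywhere an interaction column appears.
#'
#' @export
ORGANELLE_PAIRS <- apply(combn(ORGANELLES, 2), 2, paste, collapse = "-")

#' Voxel spacing in physical units
#'
#' @param sz,sy,sx physical edge lengths of one voxel along the Z, Y and X
#'   axes, in micrometres. All must be strictly positive.
#' @return A named numeric vector of class `voxel_spacing`.
#' @examples
#' sp <- voxel_spacing(0.41, 0.08, 0.08)
#' voxel_volume(sp)
#' @export
voxel_spacing <- function(sz, sy, sx) {
  s <- c(sz = as.numeric(sz), sy = as.numeric(sy), sx = as.numeric(sx))
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("voxel spacing must be strictly positive and finite", call. = FALSE)
  }
  structure(s, class = "voxel_spacing")
}

#' Physical volume of one voxel
#'
#' @param spacing a [voxel_spacing()].
#' @return Voxel volume sz*sy*sx in cubic micrometres.
#' @export
voxel_volume <- function(spacing) {
  unname(spacing[["sz"]] * spacing[["sy"]] * spacing[["sx"]])
}

as_spacing <- function(spacing) {
  if (inherits(spacing, "voxel_spacing")) return(spacing)
  if (is.numeric(spacing) && length(spacing) == 3) {
    return(voxel_spacing(spacing[[1]], spacing[[2]], spacing[[3]]))
  }
  stop("spacing must be a voxel_spacing or numeric length-3 (sz, sy, sx)",
       call. = FALSE)
}

check_grid3d <- function(grid, what) {
  if (!is.array(grid) || length(dim(grid)) != 3) {
    stop(what, ": grid must be a 3D array indexed (Z, Y, X)", call. = FALSE)
  }
  invisible(grid)
}

#' Binary semantic mask
#'
#' A 3D boolean voxel grid with physical spacing. The axis order is fixed as
#' (Z, Y, X) and voxel indices are interpreted on a regular grid with physical
#' coordinate = index * spacing.
#'
#' @param grid 3D logical (or 0/1 numeric) array indexed (plane, row, column).
#' @param spacing a [voxel_spacing()] or numeric length-3 (sz, sy, sx).
#' @return An object of class `semantic_mask`.
#' @export
semantic_mask <- function(grid, spacing) {
  check_grid3d(grid, "semantic_mask")
  if (!is.logical(grid)) {
    if (!all(grid %in% c(0, 1, NA))) {
      stop("semantic_mask: values must be binary", call. = FALSE)
    }
    grid <- array(grid > 0, dim = dim(grid))
  }
  if (anyNA(grid)) stop("semantic_mask: NA voxels not allowed", call. = FALSE)
  structure(list(grid = grid, spacing = as_spacing(spacing)),
            class = "semantic_mask")
}

#' Integer instance-label stack
#'
#' A 3D non-negative integer grid where 0 is background and positive labels
#' form the gap-free set 1..K; every label has at least one voxel.
#'
#' @param grid 3D non-negative integer array indexed (Z, Y, X).
#' @param spacing a [voxel_spacing()] or numeric length-3.
#' @param channel channel name (an organelle, pair, or mask identifier).
#' @return An object of class `label_stack` with field `n_labels`.
#' @export
label_stack <- function(grid, spacing, channel = NA_character_) {
  check_grid3d(grid, "label_stack")
  if (anyNA(grid) || any(grid < 0) || any(grid != floor(grid))) {
    stop("label_stack: grid must hold non-negative integers", call. = FALSE)
  }
  labs <- sort(unique(as.integer(grid[grid > 0])))
  k <- length(labs)
  if (k > 0 && !identical(labs, seq_len(k))) {
    stop("label_stack: labels must be the gap-free set 1..K", call. = FALSE)
  }
  storage.mode(grid) <- "integer"
  structure(list(grid = grid, spacing = as_spacing(spacing),
                 channel = channel, n_labels = k),
            class = "label_stack")
}

# Foreground of a semantic_mask, label_stack, or raw array, as logical array.
mask_grid <- function(x) {
  if (inherits(x, "semantic_mask")) return(x$grid)
  if (inherits(x, "label_stack")) return(x$grid > 0L)
  if (is.array(x)) return(x > 0)
  stop("cannot extract a voxel grid from this object", call. = FALSE)
}

obj_spacing <- function(x) {
  if (!is.null(x$spacing)) return(x$spacing)
  stop("object carries no spacing", call. = FALSE)
}

#' Cell scaffold: cell mask plus nucleus mask
#'
#' The measurement frame of one cell. Both masks are treated as exactly one
#' object each and the nucleus foreground must lie inside the cell foreground.
#'
#' @param cell,nucleus [semantic_mask()] objects sharing shape and spacing.
#' @return An object of class `cell_scaffold`.
#' @export
cell_scaffold <- function(cell, nucleus) {
  stopifnot(inherits(cell, "semantic_mask"), inherits(nucleus, "semantic_mask"))
  if (!identical(dim(cell$grid), dim(nucleus$grid))) {
    stop("cell_scaffold: cell and nucleus shapes differ (channel 'nucleus')",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(unclass(cell$spacing), unclass(nucleus$spacing)))) {
    stop("cell_scaffold: cell and nucleus spacing differ", call. = FALSE)
  }
  if (!any(cell$grid)) stop("cell_scaffold: empty cell mask", call. = FALSE)
  if (!any(nucleus$grid)) stop("cell_scaffold: empty nucleus mask", call. = FALSE)
  if (any(nucleus$grid & !cell$grid)) {
    stop("cell_scaffold: nucleus voxels outside the cell mask (nucleus-escape)",
         call. = FALSE)
  }
  structure(list(cell = cell, nucleus = nucleus, spacing = cell$spacing),
            class = "cell_scaffold")
}

#' Multi-channel cell image
#'
#' One cell's measurement bundle: a [cell_scaffold()] plus named organelle
#' channels (semantic masks or instance label stacks) and optional matching
#' intensity channels.
#'
#' @param scaffold a [cell_scaffold()].
#' @param organelles named list of [semantic_mask()] / [label_stack()]
#'   objects; names must come from [ORGANELLES].
#' @param intensity optional named list of 3D non-negative numeric arrays.
#' @return An object of class `cell_image` (validated).
#' @export
cell_image <- function(scaffold, organelles, intensity = NULL) {
  img <- structure(list(scaffold = scaffold, organelles = organelles,
                        intensity = intensity, spacing = scaffold$spacing),
                   class = "cell_image")
  validate_cell_image(img)
}

#' Validate a cell image
#'
#' Checks that all channels share shape and spacing, that the cell mask is
#' non-empty, that the nucleus lies inside the cell, and that organelle
#' channel names are recognised. Validation is idempotent.
#'
#' @param img a `cell_image`.
#' @return The validated `cell_image`, invisibly unchanged.
#' @export
validate_cell_image <- function(img) {
  stopifnot(inherits(img, "cell_image"))
  sc <- img$scaffold
  if (!inherits(sc, "cell_scaffold")) stop("missing cell scaffold", call. = FALSE)
  ref_dim <- dim(sc$cell$grid)
  ref_sp <- unclass(sc$spacing)
  if (!any(sc$cell$grid)) stop("empty-mask: channel 'cell'", call. = FALSE)
  if (any(sc$nucleus$grid & !sc$cell$grid)) {
    stop("nucleus-escape: channel 'nucleus' has voxels outside the cell mask",
         call. = FALSE)
  }
  if (length(img$organelles) > 0) {
    nm <- names(img$organelles)
    if (is.null(nm) || any(nm == "")) {
      stop("organelle channels must be named", call. = FALSE)
    }
    bad <- setdiff(nm, ORGANELLES)
    if (length(bad) > 0) {
      stop("unknown organelle channel(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (n in nm) {
      ch <- img$organelles[[n]]
      if (!inherits(ch, "semantic_mask") && !inherits(ch, "label_stack")) {
        stop("channel '", n, "' must be a semantic_mask or label_stack",
             call. = FALSE)
      }
      if (!identical(dim(ch$grid), ref_dim)) {
        stop("shape-mismatch: channel '", n, "' is ",
             paste(dim(ch$grid), collapse = "x"), " vs ",
             paste(ref_dim, collapse = "x"), call. = FALSE)
      }
      if (!isTRUE(all.equal(unclass(ch$spacing), ref_sp))) {
        stop("spacing-mismatch: channel '", n, "'", call. = FALSE)
      }
    }
  }
  if (!is.null(img$intensity)) {
    for (n in names(img$intensity)) {
      a <- img$intensity[[n]]
      check_grid3d(a, paste0("intensity '", n, "'"))
      if (!identical(dim(a), ref_dim)) {
        stop("shape-mismatch: intensity channel '", n, "'", call. = FALSE)
      }
      if (any(a < 0)) {
        stop("intensity channel '", n, "' has negative values", call. = FALSE)
      }
    }
  }
  img
}

#' Physical volume of a mask
#'
#' @param x a `semantic_mask`, `label_stack`, or logical array.
#' @param spacing required when `x` is a bare array.
#' @return Foreground voxel count times voxel volume, in cubic micrometres.
#' @export
mask_volume <- function(x, spacing = NULL) {
  sp <- if (is.null(spacing)) obj_spacing(x) else as_spacing(spacing)
  sum(mask_grid(x)) * voxel_volume(sp)
}
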