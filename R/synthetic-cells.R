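# Seeded 3D cell phantoms with known ground truth. A cell is a smoothed
# random-blob footprint extruded with a dome profile in Z over a flat base
# (an adherent cell), with an interior ellipsoidal nucleus. Organelles are
# placed by rejection sampling with configurable count, size, radial
# (perinuclear <-> peripheral) and Z biases, optional clustering, and planted
# pairwise overlap rates; the ER is a connected random-walk tube network so
# that topology metrics (tunnels) are exercised.

#' Organelle population specification for the phantom generator
#'
#' @param name organelle channel name (one of [ORGANELLES]).
#' @param count integer object count, or length-2 range sampled uniformly.
#' @param shape "sphere", "rod", or "tubes" (connected tube network, ER).
#' @param radius_um object radius in micrometres (sphere/rod/tube radius).
#' @param radius_sd SD of the per-object radius (spheres; 0 = fixed).
#' @param length_um rod length in micrometres (rods only).
#' @param n_branches,steps random-walk branches and steps per branch (tubes).
#' @param radial_bias Beta shape parameters (a, b) over the normalized radial
#'   coordinate d between 0 (nucleus edge) and 1 (cell edge).
#' @param z_bias Beta shape parameters over normalized cell height.
#' @param clustering_rate probability a new object is placed touching an
#'   existing one (merging under 26-connectivity instancing).
#' @return A list of class `organelle_spec`.
#' @export
organelle_spec <- function(name, count, shape = "sphere", radius_um = 0.25,
                           radius_sd = 0, length_um = 1.5, n_branches = 36,
                           steps = 40, radial_bias = c(2, 2),
                           z_bias = c(2, 2), clustering_rate = 0) {
  stopifnot(name %in% ORGANELLES, all(count >= 0), radius_um > 0,
            clustering_rate >= 0, clustering_rate <= 1,
            shape %in% c("sphere", "rod", "tubes"))
  structure(list(name = name, count = count, shape = shape,
                 radius_um = radius_um, radius_sd = radius_sd,
                 length_um = length_um, n_branches = n_branches,
                 steps = steps, radial_bias = radial_bias, z_bias = z_bias,
                 clustering_rate = clustering_rate),
            class = "organelle_spec")
}

#' Planted pairwise overlap specification
#'
#' When channel `a` is generated, each of its objects is placed to overlap a
#' random object of channel `b` with probability `rate`, interpenetrating by
#' about `depth` voxels. Channel `b` must be generated before channel `a`
#' (generation follows the fixed [ORGANELLES] order).
#'
#' @param a,b organelle names (the moving and the target channel).
#' @param rate target fraction of `a` objects placed to overlap `b`.
#' @param depth voxels of interpenetration (>= 1).
#' @return A list of class `interaction_spec`.
#' @export
interaction_spec <- function(a, b, rate, depth = 1) {
  stopifnot(a %in% ORGANELLES, b %in% ORGANELLES, a != b,
            rate >= 0, rate <= 1, depth >= 1)
  structure(list(a = a, b = b, rate = rate, depth = depth),
            class = "interaction_spec")
}

#' Scaffold parameters for the phantom cell
#'
#' @param dim grid dimensions (Z, Y, X) in voxels.
#' @param spacing voxel spacing (sz, sy, sx) in micrometres. The default
#'   matches the axial sampling of high-NA confocal stacks (0.41 um) with
#'   0.16 um lateral sampling, giving a ~15 um cell on a 96 x 96 footprint.
#' @param cell_radius_frac mean footprint radius as a fraction of the
#'   smaller lateral grid extent.
#' @param irregularity amplitude of the low-order harmonics perturbing the
#'   footprint radius (0 = circular disc).
#' @param nucleus_frac nucleus lateral radius as a fraction of the cell
#'   radius.
#' @param dome_frac peak cell height as a fraction of the Z extent.
#' @return A list of class `scaffold_params`.
#' @export
scaffold_params <- function(dim = c(24, 96, 96),
                            spacing = c(0.41, 0.16, 0.16),
                            cell_radius_frac = 0.40, irregularity = 0.12,
                            nucleus_frac = 0.34, dome_frac = 0.80) {
  structure(list(dim = as.integer(dim), spacing = as_spacing(spacing),
                 cell_radius_frac = cell_radius_frac,
                 irregularity = irregularity, nucleus_frac = nucleus_frac,
                 dome_frac = dome_frac),
            class = "scaffold_params")
}

# ellipsoid voxel offsets for a physical radius, as an offset matrix (z,y,x)
ellipsoid_offsets <- function(r_um, spv) {
  rz <- floor(r_um / spv[1]); ry <- floor(r_um / spv[2]); rx <- floor(r_um / spv[3])
  off <- as.matrix(expand.grid(z = -rz:rz, y = -ry:ry, x = -rx:rx))
  keep <- (off[, 1] * spv[1])^2 + (off[, 2] * spv[2])^2 +
    (off[, 3] * spv[3])^2 <= r_um^2 + 1e-12
  off[keep, , drop = FALSE]
}

# build the cell + nucleus scaffold; returns grids plus placement geometry
build_phantom_scaffold <- function(params) {
  dm <- params$dim
  nz <- dm[1]; ny <- dm[2]; nx <- dm[3]
  cy <- ny / 2 + 0.5; cx <- nx / 2 + 0.5
  r0 <- params$cell_radius_frac * min(ny, nx)
  amp <- params$irregularity * rnorm(4) / seq(1, 2.5, length.out = 4)
  phi <- runif(4, 0, 2 * pi)
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  th <- atan2(yy - cy, xx - cx)
  rr <- sqrt((yy - cy)^2 + (xx - cx)^2)
  rad <- r0 * (1 + Reduce(`+`, lapply(1:4, function(k)
    amp[k] * cos((k + 1) * th + phi[k]))))
  rad <- pmax(rad, 0.55 * r0)
  fp <- rr <= rad
  hmax <- max(3, round(params$dome_frac * nz))
  z0 <- 2L
  hh <- matrix(0L, ny, nx)
  hh[fp] <- pmax(2L, round(hmax * sqrt(pmax(0, 1 - (rr[fp] / rad[fp])^2))))
  hh[fp] <- pmin(hh[fp], nz - z0)
  cell <- array(FALSE, dm)
  for (z in seq_len(nz)) {
    cell[z, , ] <- fp & (z >= z0) & (z < z0 + hh)
  }
  # nucleus: interior ellipsoid around the footprint center
  spv <- unclass(params$spacing)
  nr <- params$nucleus_frac * r0
  hcen <- hh[round(cy), round(cx)]
  ncz <- z0 + max(1, round(0.40 * hcen))
  nrz <- max(1, round(0.30 * hcen))
  zz <- array(rep(seq_len(nz), ny * nx), dm)
  yyy <- aperm(array(rep(yy, nz), c(ny, nx, nz)), c(3, 1, 2))
  xxx <- aperm(array(rep(xx, nz), c(ny, nx, nz)), c(3, 1, 2))
  nuc <- ((zz - ncz) / nrz)^2 + ((yyy - cy) / nr)^2 + ((xxx - cx) / nr)^2 <= 1
  nuc <- nuc & cell
  if (!any(nuc)) stop("degenerate scaffold: empty nucleus", call. = FALSE)
  list(cell = cell, nucleus = nuc, footprint = fp, height = hh, z0 = z0,
       params = params)
}

# radial coordinate d over the footprint, as in the ring geometry
footprint_radial_d <- function(fp, nfp) {
  d_nuc <- pmax(as.matrix(EBImage::distmap(1 - nfp)) - 1, 0)
  d_edge <- pmax(as.matrix(EBImage::distmap(fp * 1)) - 1, 0)
  tot <- d_nuc + d_edge
  ifelse(tot > 0, d_nuc / tot, 1)
}

# dilate a voxel index matrix by the 26-neighborhood, clipped to the grid
dilate26_idx <- function(vox, dm) {
  sh <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- do.call(rbind, lapply(seq_len(nrow(sh)), function(i)
    sweep(vox, 2, sh[i, ], `+`)))
  keep <- out[, 1] >= 1 & out[, 1] <= dm[1] &
    out[, 2] >= 1 & out[, 2] <= dm[2] & out[, 3] >= 1 & out[, 3] <= dm[3]
  out[keep, , drop = FALSE]
}

#' Generate one synthetic cell phantom
#'
#' Deterministic for a fixed seed. Organelle foreground is constrained to
#' the cell mask and kept out of the nucleus; with clustering rate 0, placed
#' objects of one channel are separated by more than one voxel, so instance
#' counts equal the recorded ground-truth counts.
#'
#' @param specs list of [organelle_spec()] (at most one per organelle).
#' @param interactions list of [interaction_spec()].
#' @param scaffold a [scaffold_params()].
#' @param seed integer seed.
#' @param max_attempts placement attempts per object before an
#'   infeasible-placement error.
#' @return A list: `image` (a validated [cell_image()]) and `truth`
#'   (ground-truth record: per-organelle realized counts, volumes,
#'   centroids, per-pair planted overlap counts, the seed and parameters).
#' @export
generate_cell <- function(specs, interactions = list(),
                          scaffold = scaffold_params(), seed = 1,
                          max_attempts = 1000) {
  nm <- vapply(specs, function(s) s$name, "")
  if (anyDuplicated(nm)) stop("duplicate organelle specs", call. = FALSE)
  set.seed(seed)
  sc <- build_phantom_scaffold(scaffold)
  dm <- scaffold$dim
  spv <- unclass(scaffold$spacing)
  vv <- voxel_volume(scaffold$spacing)
  allowed <- sc$cell & !sc$nucleus
  nfp <- colSums(sc$nucleus, dims = 1) > 0
  dmap <- footprint_radial_d(sc$footprint, nfp)
  # candidate placement columns: footprint outside the nucleus footprint
  cand <- which(sc$footprint & !nfp, arr.ind = TRUE)
  cand_d <- pmin(pmax(dmap[cand], 0.02), 0.98)
  channels <- list()
  truth_org <- list()
  placed <- list()   # per channel: list of voxel index matrices per object
  overlaps <- list()
  gen_order <- ORGANELLES[ORGANELLES %in% nm]
  for (org in gen_order) {
    spec <- specs[[which(nm == org)]]
    occ <- array(FALSE, dm)
    blocked <- array(FALSE, dm)
    objs <- list()
    n_obj <- if (length(spec$count) == 2) {
      sample(spec$count[1]:spec$count[2], 1)
    } else as.integer(spec$count)
    my_inter <- Filter(function(i) i$a == org, interactions)
    planted <- 0L
    if (spec$shape == "tubes" && n_obj > 0) {
      vox <- grow_tube_network(spec, sc, allowed, spv)
      if (nrow(vox) > 0) {
        occ[vox] <- TRUE
        objs[[1]] <- vox
      }
    } else if (n_obj > 0) {
      w <- stats::dbeta(cand_d, spec$radial_bias[1], spec$radial_bias[2])
      w <- w / sum(w)
      for (k in seq_len(n_obj)) {
        force_pair <- NULL
        if (length(my_inter) > 0) {
          it <- my_inter[[1]]
          tgt <- placed[[it$b]]
          if (!is.null(tgt) && length(tgt) > 0 && runif(1) < it$rate) {
            force_pair <- it
          }
        }
        cluster_this <- is.null(force_pair) && any(occ) &&
          runif(1) < spec$clustering_rate
        ok <- FALSE
        for (attempt in seq_len(max_attempts)) {
          # forced or clustered placement that cannot find room falls back
          # to unbiased placement for the second half of the attempts
          fp <- if (attempt <= max_attempts / 2) force_pair else NULL
          cl <- cluster_this && attempt <= max_attempts / 2
          vox <- place_one_object(spec, sc, allowed, spv, cand, w, placed,
                                  fp, cl, occ)
          if (is.null(vox) || nrow(vox) == 0) next
          if (!cl) {
            if (any(blocked[vox])) next
          }
          occ[vox] <- TRUE
          blk <- dilate26_idx(vox, dm)
          blocked[blk] <- TRUE
          objs[[length(objs) + 1]] <- vox
          if (!is.null(fp)) planted <- planted + 1L
          ok <- TRUE
          break
        }
        if (!ok) {
          stop("infeasible-placement: organelle ", org, " object ", k,
               " after ", max_attempts, " attempts", call. = FALSE)
        }
      }
    }
    channels[[org]] <- semantic_mask(occ, scaffold$spacing)
    placed[[org]] <- objs
    truth_org[[org]] <- list(
      count = length(objs),
      volumes = vapply(objs, function(v) nrow(v) * vv, 0),
      centroids = if (length(objs) > 0) {
        t(vapply(objs, function(v) colMeans(sweep(v - 1, 2, spv, `*`)), numeric(3)))
      } else matrix(numeric(0), 0, 3),
      planted_overlaps = planted
    )
    if (length(my_inter) > 0) {
      it <- my_inter[[1]]
      overlaps[[paste0(it$a, "->", it$b)]] <-
        list(rate = it$rate, planted = planted, n_objects = length(objs))
    }
  }
  img <- cell_image(
    cell_scaffold(semantic_mask(sc$cell, scaffold$spacing),
                  semantic_mask(sc$nucleus, scaffold$spacing)),
    organelles = channels
  )
  truth <- structure(list(organelles = truth_org, overlaps = overlaps,
                          seed = seed, specs = specs,
                          interactions = interactions, scaffold = scaffold),
                     class = "ground_truth")
  list(image = img, truth = truth)
}

# carve one sphere or rod; returns a voxel index matrix or NULL
place_one_object <- function(spec, sc, allowed, spv, cand, w, placed,
                             force_pair, cluster_this, occ) {
  dm <- dim(allowed)
  r <- max(0.05, spec$radius_um + if (spec$radius_sd > 0)
    rnorm(1, 0, spec$radius_sd) else 0)
  if (!is.null(force_pair)) {
    tgt <- placed[[force_pair$b]]
    obj <- tgt[[sample.int(length(tgt), 1)]]
    b0 <- obj[sample.int(nrow(obj), 1), ]
    u <- rnorm(3); u[1] <- u[1] * 0.3
    u <- u / sqrt(sum(u^2))
    shift_px <- (r / spv[3]) - force_pair$depth
    ctr <- round(b0 + u * max(0, shift_px))
  } else if (cluster_this) {
    own <- which(occ, arr.ind = TRUE)
    b0 <- own[sample.int(nrow(own), 1), ]
    u <- rnorm(3); u[1] <- u[1] * 0.3
    u <- u / sqrt(sum(u^2))
    ctr <- round(b0 + u * max(1, r / spv[3]))
  } else {
    pick <- sample.int(nrow(cand), 1, prob = w)
    yx <- cand[pick, ]
    z0 <- sc$z0
    h <- sc$height[yx[1], yx[2]]
    if (h < 1) return(NULL)
    zq <- rbeta(1, spec$z_bias[1], spec$z_bias[2])
    z <- z0 + floor(zq * h)
    ctr <- c(z, yx[1], yx[2])
  }
  if (any(ctr < 1) || any(ctr > dm)) return(NULL)
  if (spec$shape == "sphere") {
    off <- ellipsoid_offsets(r, spv)
    vox <- sweep(off, 2, ctr, `+`)
  } else {  # rod: capsule around a random segment through the center
    u <- rnorm(3); u[1] <- u[1] * 0.25
    u <- u / sqrt(sum(u^2))
    hl <- spec$length_um / 2
    ext <- ceiling((hl + r) / spv)
    off <- as.matrix(expand.grid(z = -ext[1]:ext[1], y = -ext[2]:ext[2],
                                 x = -ext[3]:ext[3]))
    p <- sweep(off, 2, spv, `*`)
    tproj <- pmin(pmax(p %*% u, -hl), hl)
    dd2 <- rowSums((p - tproj %*% t(u))^2)
    vox <- sweep(off[dd2 <= r^2, , drop = FALSE], 2, ctr, `+`)
  }
  keep <- vox[, 1] >= 1 & vox[, 1] <= dm[1] & vox[, 2] >= 1 &
    vox[, 2] <= dm[2] & vox[, 3] >= 1 & vox[, 3] <= dm[3]
  vox <- vox[keep, , drop = FALSE]
  vox <- vox[allowed[vox], , drop = FALSE]
  if (nrow(vox) == 0) return(NULL)
  vox
}

# connected ER-like tube network: random-walk skeleton branches started from
# existing skeleton voxels (a tree plus chance crossings -> tunnels), dilated
# to the tube radius
grow_tube_network <- function(spec, sc, allowed, spv) {
  dm <- dim(allowed)
  nfp <- colSums(sc$nucleus, dims = 1) > 0
  ni <- which(nfp, arr.ind = TRUE)
  cyx <- colMeans(ni)
  skel <- matrix(numeric(0), 0, 3)
  for (b in seq_len(spec$n_branches)) {
    if (nrow(skel) == 0) {
      start_candidates <- which(allowed, arr.ind = TRUE)
      dctr <- sqrt((start_candidates[, 2] - cyx[1])^2 +
                     (start_candidates[, 3] - cyx[2])^2)
      pos <- start_candidates[which.min(dctr), ] * 1.0
    } else {
      pos <- skel[sample.int(nrow(skel), 1), ] + 0.0
    }
    th <- runif(1, 0, 2 * pi)
    zdrift <- rnorm(1, 0, 0.10)
    for (s in seq_len(spec$steps)) {
      th <- th + rnorm(1, 0, 0.35)
      stuck <- 0
      repeat {
        cand <- pos + c(zdrift + rnorm(1, 0, 0.08), sin(th), cos(th))
        ci <- round(cand)
        inside <- all(ci >= 1) && all(ci <= dm) && allowed[ci[1], ci[2], ci[3]]
        if (inside) break
        th <- runif(1, 0, 2 * pi)
        zdrift <- -zdrift
        stuck <- stuck + 1
        if (stuck > 8) break
      }
      if (stuck > 8) break
      pos <- cand
      skel <- rbind(skel, round(pos))
    }
  }
  if (nrow(skel) == 0) return(matrix(integer(0), 0, 3))
  skel <- unique(round(skel))
  off <- ellipsoid_offsets(spec$radius_um, spv)
  vox <- unique(do.call(rbind, lapply(seq_len(nrow(off)), function(i)
    sweep(skel, 2, off[i, ], `+`))))
  keep <- vox[, 1] >= 1 & vox[, 1] <= dm[1] & vox[, 2] >= 1 &
    vox[, 2] <= dm[2] & vox[, 3] >= 1 & vox[, 3] <= dm[3]
  vox <- vox[keep, , drop = FALSE]
  storage.mode(vox) <- "integer"
  vox[allowed[vox], , drop = FALSE]
}

#' Phantom presets emulating the two cell types
#'
#' Two parameter sets with documented contrasts: `neuron_like` has a higher
#' mitochondrial count and total volume, a denser ER network, and a higher
#' MT-on-ER planted overlap rate; `astrocyte_like` has more and larger
#' lysosomes with a strong perinuclear radial bias, and a higher PO-on-LS
#' planted overlap rate (a larger fraction of peroxisomes touching
#' lysosomes). Lipid-droplet counts are sampled around means of ~12 (neuron)
#' and ~19 (astrocyte).
#'
#' @param name "neuron_like" or "astrocyte_like".
#' @return A list: `specs`, `interactions`, `scaffold`.
#' @export
phantom_preset <- function(name) {
  if (!name %in% c("neuron_like", "astrocyte_like")) {
    stop("unknown preset: ", name, call. = FALSE)
  }
  common <- list(
    GL = organelle_spec("GL", count = c(6, 10), shape = "rod",
                        radius_um = 0.25, length_um = 1.2,
                        radial_bias = c(1, 5), z_bias = c(2, 2)),
    PO_shape = list(radius_um = 0.18)
  )
  if (name == "neuron_like") {
    specs <- list(
      organelle_spec("ER", count = 1, shape = "tubes", radius_um = 0.18,
                     n_branches = 40, steps = 42),
      common$GL,
      organelle_spec("LD", count = c(9, 16), radius_um = 0.25,
                     radial_bias = c(2.2, 1.3)),
      organelle_spec("LS", count = c(16, 24), radius_um = 0.30,
                     radius_sd = 0.06, radial_bias = c(1.8, 1.8)),
      organelle_spec("MT", count = c(50, 70), shape = "rod",
                     radius_um = 0.22, length_um = 1.4,
                     radial_bias = c(1.6, 1.6), z_bias = c(2, 2.2)),
      organelle_spec("PO", count = c(24, 36), radius_um = 0.17,
                     radial_bias = c(2, 1.4))
    )
    inter <- list(interaction_spec("MT", "ER", rate = 0.55, depth = 1),
                  interaction_spec("PO", "LS", rate = 0.15, depth = 1))
  } else {
    specs <- list(
      organelle_spec("ER", count = 1, shape = "tubes", radius_um = 0.18,
                     n_branches = 30, steps = 42),
      common$GL,
      organelle_spec("LD", count = c(15, 22), radius_um = 0.25,
                     radial_bias = c(2.2, 1.3)),
      organelle_spec("LS", count = c(30, 42), radius_um = 0.38,
                     radius_sd = 0.13, radial_bias = c(0.8, 6)),
      organelle_spec("MT", count = c(24, 36), shape = "rod",
                     radius_um = 0.22, length_um = 1.8,
                     radial_bias = c(1.6, 1.6), z_bias = c(2, 2)),
      organelle_spec("PO", count = c(16, 26), radius_um = 0.22,
                     radial_bias = c(2, 1.4))
    )
    inter <- list(interaction_spec("MT", "ER", rate = 0.25, depth = 1),
                  interaction_spec("PO", "LS", rate = 0.60, depth = 1))
  }
  list(specs = specs, interactions = inter, scaffold = scaffold_params())
}

#' Generate a group of preset phantoms
#'
#' @param preset preset name, see [phantom_preset()].
#' @param seeds integer vector; one cell is generated per seed.
#' @return List of `generate_cell()` results.
#' @export
simulate_cells <- function(preset, seeds) {
  p <- phantom_preset(preset)
  lapply(seeds, function(s)
    generate_cell(p$specs, p$interactions, p$scaffold, seed = s))
}

#' Generate synthetic particle tracks
#'
#' Directed tracks move along a fixed random heading at the given speed
#' (plus optional isotropic positional noise, so tortuosity tends to 1 as
#' noise vanishes); diffusive tracks take isotropic Gaussian steps whose
#' expected step length matches `speed * interval`; stationary tracks do not
#' move.
#'
#' @param n_tracks number of tracks.
#' @param motion "directed", "diffusive" or "stationary".
#' @param speed_um_s nominal speed in micrometres per second.
#' @param frames number of frames (>= 2).
#' @param interval_s frame interval in seconds (default 5).
#' @param noise_sd SD of additive positional noise in micrometres.
#' @param seed integer seed.
#' @return A list of track data.frames (track_id, frame, x, y) with the
#'   frame interval attached as attribute `interval_s`.
#' @export
generate_tracks <- function(n_tracks, motion = c("directed", "diffusive",
                                                 "stationary"),
                            speed_um_s = 0.2, frames = 60, interval_s = 5,
                            noise_sd = 0, seed = 1) {
  motion <- match.arg(motion)
  if (frames < 2) stop("frames must be >= 2", call. = FALSE)
  set.seed(seed)
  step_len <- speed_um_s * interval_s
  lapply(seq_len(n_tracks), function(tid) {
    if (motion == "directed") {
      th <- runif(1, 0, 2 * pi)
      dx <- rep(step_len * cos(th), frames - 1)
      dy <- rep(step_len * sin(th), frames - 1)
    } else if (motion == "diffusive") {
      s <- step_len / sqrt(pi / 2) / sqrt(2)  # E|step| = step_len
      dx <- rnorm(frames - 1, 0, s * sqrt(2))
      dy <- rnorm(frames - 1, 0, s * sqrt(2))
    } else {
      dx <- dy <- rep(0, frames - 1)
    }
    x <- cumsum(c(0, dx)) + if (noise_sd > 0) rnorm(frames, 0, noise_sd) else 0
    y <- cumsum(c(0, dy)) + if (noise_sd > 0) rnorm(frames, 0, noise_sd) else 0
    structure(data.frame(track_id = tid, frame = seq_len(frames) - 1L,
                         x = x, y = y),
              interval_s = interval_s)
  })
}
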