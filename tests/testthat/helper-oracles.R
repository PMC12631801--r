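# Independent oracles and fixture builders used across the suite.

# random binary 3D mask
make_random_mask <- function(dm, p = 0.3, seed = 1) {
  set.seed(seed)
  array(runif(prod(dm)) < p, dm)
}

# --- connected components oracle: adjacency graph + igraph components ------
oracle_label_cc26 <- function(grid) {
  out <- array(0L, dim(grid))
  idx <- which(grid)
  if (length(idx) == 0) return(out)
  cc <- arrayInd(idx, dim(grid))
  n <- nrow(cc)
  edges <- list()
  for (i in seq_len(n)) {
    d <- abs(sweep(cc, 2, cc[i, ]))
    nb <- which(apply(d, 1, max) == 1)
    nb <- nb[nb > i]
    if (length(nb) > 0) edges[[length(edges) + 1]] <- cbind(i, nb)
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges) > 0) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  comp <- igraph::components(g)$membership
  # relabel by first voxel in raster order (Z slowest, X fastest)
  ord <- order(cc[, 1], cc[, 2], cc[, 3])
  relab <- integer(max(comp))
  nxt <- 0L
  for (i in ord) {
    if (relab[comp[i]] == 0L) {
      nxt <- nxt + 1L
      relab[comp[i]] <- nxt
    }
  }
  out[idx] <- relab[comp]
  out
}

# --- Euler characteristic oracle: explicit cubical-complex cell counting ---
oracle_euler <- function(grid) {
  cc <- arrayInd(which(grid), dim(grid))
  if (nrow(cc) == 0) return(0L)
  key <- function(m) unique(paste(m[, 1], m[, 2], m[, 3]))
  verts <- edges <- faces <- character(0)
  for (i in seq_len(nrow(cc))) {
    z <- cc[i, 1]; y <- cc[i, 2]; x <- cc[i, 3]
    corners <- as.matrix(expand.grid(z + 0:1, y + 0:1, x + 0:1))
    verts <- c(verts, paste(corners[, 1], corners[, 2], corners[, 3]))
    # edges: 12 per cube, identified by midpoint * 2
    for (d in 1:3) {
      off <- expand.grid(0:1, 0:1)
      for (r in seq_len(nrow(off))) {
        base <- c(z, y, x) * 2
        mid <- base
        mid[d] <- mid[d] + 1
        oth <- setdiff(1:3, d)
        mid[oth] <- mid[oth] + 2 * unlist(off[r, ])
        edges <- c(edges, paste(mid[1], mid[2], mid[3]))
      }
    }
    # faces: 6 per cube, identified by center * 2
    for (d in 1:3) {
      for (s in 0:1) {
        ctr <- c(z, y, x) * 2 + 1
        ctr[d] <- c(z, y, x)[d] * 2 + 2 * s
        faces <- c(faces, paste(ctr[1], ctr[2], ctr[3]))
      }
    }
  }
  length(unique(verts)) - length(unique(edges)) + length(unique(faces)) -
    nrow(cc)
}

# --- convex-image oracle via scipy (independent qhull implementation) ------
# takes a list of voxel-coordinate matrices; returns convex-image counts,
# NA for objects scipy reports as degenerate
scipy_convex_counts <- function(coord_list) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(lapply(coord_list, unname), infile)
  script <- '
import json, sys
import numpy as np
from scipy.spatial import ConvexHull, QhullError
objs = json.load(open(sys.argv[1]))
res = []
for pts in objs:
    P = np.asarray(pts, dtype=float)
    try:
        hull = ConvexHull(P)
    except QhullError:
        res.append(None)
        continue
    lo = P.min(axis=0).astype(int); hi = P.max(axis=0).astype(int)
    zz, yy, xx = np.meshgrid(*[np.arange(l, h + 1) for l, h in zip(lo, hi)],
                             indexing="ij")
    Q = np.stack([zz.ravel(), yy.ravel(), xx.ravel()], axis=1).astype(float)
    A = hull.equations[:, :3]; b = hull.equations[:, 3]
    inside = (Q @ A.T + b <= 1e-7).all(axis=1)
    res.append(int(inside.sum()))
json.dump(res, open(sys.argv[2], "w"))
'
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", c(sf, infile, outfile), stdout = FALSE,
                    stderr = FALSE)
  if (status != 0) stop("python convex-hull oracle failed")
  vals <- jsonlite::fromJSON(outfile, simplifyVector = FALSE)
  vapply(vals, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)
}

# --- exact Mann-Whitney oracle by enumeration over rank assignments --------
oracle_mwu_p <- function(xa, xb) {
  na <- length(xa); nb <- length(xb)
  pooled <- c(xa, xb)
  combs <- combn(na + nb, na)
  u_of <- function(sel) {
    a <- pooled[sel]; b <- pooled[-sel]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  us <- apply(combs, 2, u_of)
  u_obs <- u_of(seq_len(na))
  mu <- na * nb / 2
  if (u_obs > mu) {
    p <- 2 * mean(us >= u_obs)
  } else if (u_obs < mu) {
    p <- 2 * mean(us <= u_obs)
  } else {
    p <- 1
  }
  min(p, 1)
}

# --- plain (one-stage) BH step-up for cross-checking the BKY stages --------
bh_reject <- function(p, level) {
  m <- length(p)
  o <- order(p)
  below <- p[o] <= level * seq_len(m) / m
  r <- if (any(below)) max(which(below)) else 0L
  rej <- logical(m)
  if (r > 0) rej[o[seq_len(r)]] <- TRUE
  rej
}

# --- fixtures --------------------------------------------------------------
# circular disc cell with a central nucleus, unit spacing
make_disc_cell <- function(nz = 8, ny = 40, nx = 40, r_cell = 18, r_nuc = 6,
                           z_cell = 2:7, z_nuc = 3:5) {
  cell <- array(FALSE, c(nz, ny, nx))
  nuc <- array(FALSE, c(nz, ny, nx))
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  for (y in seq_len(ny)) {
    r <- sqrt((y - cy)^2 + (seq_len(nx) - cx)^2)
    cell[z_cell, y, r <= r_cell] <- TRUE
    nuc[z_nuc, y, r <= r_nuc] <- TRUE
  }
  cell_scaffold(semantic_mask(cell, c(1, 1, 1)),
                semantic_mask(nuc, c(1, 1, 1)))
}

# digitized sphere of radius r voxels, isotropic unit spacing
make_sphere <- function(r, pad = 3) {
  n <- 2 * r + 2 * pad + 1
  ctr <- r + pad + 1
  g <- array(FALSE, c(n, n, n))
  for (z in seq_len(n)) for (y in seq_len(n)) {
    g[z, y, ] <- (z - ctr)^2 + (y - ctr)^2 + (seq_len(n) - ctr)^2 <= r^2
  }
  g
}

# small but complete six-channel phantom for signature tests
make_small_cell <- function(seed = 1) {
  sp <- scaffold_params(dim = c(12, 48, 48), spacing = c(0.41, 0.16, 0.16))
  specs <- list(
    organelle_spec("ER", count = 1, shape = "tubes", radius_um = 0.18,
                   n_branches = 10, steps = 20),
    organelle_spec("GL", count = 3, shape = "rod", radius_um = 0.25,
                   length_um = 1.0, radial_bias = c(1, 4)),
    organelle_spec("LD", count = 4, radius_um = 0.25),
    organelle_spec("LS", count = 6, radius_um = 0.3),
    organelle_spec("MT", count = 8, shape = "rod", radius_um = 0.22,
                   length_um = 1.2),
    organelle_spec("PO", count = 5, radius_um = 0.2)
  )
  inter <- list(interaction_spec("PO", "LS", rate = 0.5, depth = 1))
  generate_cell(specs, inter, sp, seed = seed)
}
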