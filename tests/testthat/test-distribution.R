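test_that("concentric-disc phantom yields annular rings of equal thickness", {
  sc <- make_disc_cell()
  xy <- build_xy_regions(sc)
  cy <- 20.5; cx <- 20.5
  # along the +x half-row through the center, rings increase monotonically
  row <- xy$ring[20, 21:38]
  expect_true(all(diff(row) >= 0))
  expect_equal(row[1], 1L)          # nucleus pixel
  expect_equal(row[length(row)], 5L)  # cell boundary pixel
  # ring boundaries fall near the analytic radii 6 + 2.4 k
  for (k in 1:4) {
    r_b <- 6 + 2.4 * k
    inner <- xy$ring[20, 21 + floor(r_b) - 2]
    outer <- xy$ring[20, 21 + ceiling(r_b) + 1]
    expect_lte(inner, k)
    expect_gte(outer, k + 1)
  }
  expect_equal(sum(xy$ring_volume), mask_volume(sc$cell))
  # every footprint pixel has exactly one ring and one wedge
  fp <- colSums(sc$cell$grid, dims = 1) > 0
  expect_true(all(xy$ring[fp] %in% 1:5))
  expect_true(all(xy$wedge[fp] %in% 1:8))
})

test_that("Z bins split the cell plane range with the documented remainder rule", {
  sc20 <- make_disc_cell(nz = 24, z_cell = 3:22, z_nuc = 10:14)
  z20 <- build_z_regions(sc20)
  expect_equal(as.integer(table(z20$bins[z20$bins > 0])), rep(2L, 10))
  sc23 <- make_disc_cell(nz = 27, z_cell = 2:24, z_nuc = 10:14)
  z23 <- build_z_regions(sc23)
  sizes <- as.integer(table(z23$bins[z23$bins > 0]))
  expect_equal(sizes, c(3L, 3L, 3L, rep(2L, 7)))  # extras to bottom bins
  sc5 <- make_disc_cell(nz = 8, z_cell = 2:6, z_nuc = 3:4)
  z5 <- build_z_regions(sc5)
  expect_equal(sum(z5$bin_volume > 0), 5)
  expect_equal(sum(z5$bin_volume), mask_volume(sc5$cell))
})

test_that("normalized profile follows the stated formula on a hand-built case", {
  # two rings: ring 1 cell volume 40, ring 2 cell volume 120 (vv = 1)
  ny <- 8; nx <- 8; nz <- 4
  ring <- matrix(0L, ny, nx)
  ring[1:2, 1:5] <- 1L   # 10 columns
  ring[3:8, 1:5] <- 2L   # 30 columns
  cell <- array(FALSE, c(nz, ny, nx))
  for (y in 1:ny) for (x in 1:nx) if (ring[y, x] > 0) cell[, y, x] <- TRUE
  regions <- structure(list(
    ring = ring, wedge = matrix(1L, ny, nx),
    ring_volume = c(40, 120), rw_volume = matrix(c(40, 120), 2, 1),
    cell_volume = 160, n_rings = 2, n_wedges = 1,
    spacing = voxel_spacing(1, 1, 1)), class = "xy_regions")
  obj <- array(FALSE, c(nz, ny, nx))
  obj[1, 1, 1:4] <- TRUE   # 4 voxels in ring 1
  obj[1, 4, 1:4] <- TRUE   # 4 voxels in ring 2
  p <- profile_regions(obj, regions)
  expect_equal(p$raw, c(4, 4))
  expect_equal(p$total, 8)
  expect_equal(p$n, c(0.5 / 0.25, 0.5 / 0.75))
  s <- summarize_distribution(p, cv = FALSE)
  expect_equal(unname(s["mode"]), 1)
  w <- p$n / sum(p$n)
  mu <- sum(w * 1:2)
  expect_equal(unname(s["SD"]), sqrt(sum(w * (1:2 - mu)^2)))
  expect_equal(unname(round(s["SD"], 3)), 0.433)
})

test_that("an object equal to the cell mask has unit normalized volume everywhere", {
  sc <- make_disc_cell()
  xy <- build_xy_regions(sc)
  zr <- build_z_regions(sc)
  px <- profile_regions(sc$cell, xy)
  expect_equal(px$n, rep(1, 5))
  pz <- profile_regions(sc$cell, zr)
  expect_equal(pz$n[zr$bin_volume > 0], rep(1, sum(zr$bin_volume > 0)))
  # SD of a uniform index distribution over 5 rings: closed form
  s <- summarize_distribution(px)
  expect_equal(unname(s["SD"]), sqrt(mean((1:5 - 3)^2)))
  expect_equal(unname(s["median_CV"]), 0, tolerance = 1e-10)
})

test_that("volume is conserved across regions for arbitrary objects", {
  sc <- make_disc_cell()
  xy <- build_xy_regions(sc)
  zr <- build_z_regions(sc)
  for (i in 1:5) {
    obj <- make_random_mask(dim(sc$cell$grid), 0.2, seed = 500 + i) &
      sc$cell$grid
    vol <- sum(obj)
    expect_equal(sum(profile_regions(obj, xy)$raw), vol)
    expect_equal(sum(profile_regions(obj, zr)$raw), vol)
  }
})

test_that("distribution summaries handle point masses and empty profiles", {
  sc <- make_disc_cell()
  xy <- build_xy_regions(sc)
  zr <- build_z_regions(sc)
  # all volume in one Z bin
  obj <- array(FALSE, dim(sc$cell$grid))
  obj[3, , ] <- sc$cell$grid[3, , ]
  pz <- profile_regions(obj, zr)
  s <- summarize_distribution(pz, cv = FALSE)
  expect_equal(unname(s["SD"]), 0)
  # empty object
  pe <- profile_regions(array(FALSE, dim(sc$cell$grid)), xy)
  expect_true(pe$empty)
  se <- summarize_distribution(pe)
  expect_true(all(is.na(se)))
})

test_that("rotating the disc phantom by 90 degrees leaves ring assignments unchanged", {
  sc <- make_disc_cell()
  xy <- build_xy_regions(sc)
  rot <- function(a) {
    out <- array(FALSE, dim(a)[c(1, 3, 2)])
    for (z in seq_len(dim(a)[1])) out[z, , ] <- t(a[z, , ])[, rev(seq_len(dim(a)[2]))]
    out
  }
  sc2 <- cell_scaffold(semantic_mask(rot(sc$cell$grid), c(1, 1, 1)),
                       semantic_mask(rot(sc$nucleus$grid), c(1, 1, 1)))
  xy2 <- build_xy_regions(sc2)
  expect_equal(sort(table(xy$ring[xy$ring > 0])),
               sort(table(xy2$ring[xy2$ring > 0])))
})
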