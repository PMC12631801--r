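measure_one <- function(grid, spacing = c(1, 1, 1)) {
  measure_objects(label_instances(semantic_mask(grid, spacing)))
}

test_that("closed-form metrics on elementary solids", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  r1 <- measure_one(one)
  expect_equal(r1$volume, 1)
  expect_equal(r1$equivalent_diameter, (6 / pi)^(1 / 3))
  expect_equal(r1$extent, 1)
  expect_equal(r1$solidity, 1)
  expect_equal(r1$euler_number, 1)
  expect_equal(r1$axis_major_length, 0)

  cube <- array(FALSE, c(6, 6, 6)); cube[2:5, 2:5, 2:5] <- TRUE
  rc <- measure_one(cube)
  expect_equal(rc$volume, 64)
  expect_equal(rc$extent, 1)
  expect_equal(rc$solidity, 1)
  expect_equal(rc$euler_number, 1)
})

test_that("a hollow shell has Euler number 2 (one enclosed cavity)", {
  sh <- array(FALSE, c(7, 7, 7))
  sh[2:6, 2:6, 2:6] <- TRUE
  sh[3:5, 3:5, 3:5] <- FALSE
  expect_equal(euler_number3d(sh), 2L)
  expect_equal(euler_number3d(sh), oracle_euler(sh))
  rs <- measure_one(sh)
  expect_equal(rs$euler_number, 2)
})

test_that("digitized sphere converges to the analytic limits", {
  r <- 10
  g <- make_sphere(r)
  rec <- measure_one(g)
  v_true <- 4 / 3 * pi * r^3
  expect_lt(abs(rec$volume - v_true) / v_true, 0.02)
  expect_lt(abs(rec$equivalent_diameter - 2 * r) / (2 * r), 0.01)
  expect_lt(abs(rec$surface_area - 4 * pi * r^2) / (4 * pi * r^2), 0.05)
  expect_gt(rec$solidity, 0.95)
})

test_that("shape metrics agree with brute-force oracles on random objects", {
  for (i in 1:12) {
    dm <- c(sample(5:12, 1), sample(5:12, 1), sample(5:12, 1))
    g <- make_random_mask(dm, runif(1, 0.2, 0.5), seed = 200 + i)
    if (!any(g)) next
    lab <- label_instances(semantic_mask(g, c(1, 1, 1)))
    rec <- measure_objects(lab)
    for (k in seq_len(lab$n_labels)) {
      vox <- which(lab$grid == k)
      cc <- arrayInd(vox, dm)
      expect_equal(rec$volume[k], length(vox))
      bb <- apply(cc, 2, function(v) diff(range(v)) + 1)
      expect_equal(rec$extent[k], length(vox) / prod(bb))
      obj <- array(FALSE, dm); obj[vox] <- TRUE
      expect_equal(rec$euler_number[k], oracle_euler(obj))
      expect_equal(rec$equivalent_diameter[k],
                   (6 * rec$volume[k] / pi)^(1 / 3))
    }
  }
})

test_that("shape metrics are translation invariant", {
  g <- make_sphere(4, pad = 2)
  base <- measure_one(g)
  big <- array(FALSE, dim(g) + c(5, 7, 3))
  big[5 + seq_len(dim(g)[1]), 7 + seq_len(dim(g)[2]), 3 + seq_len(dim(g)[3])] <- g
  shifted <- measure_one(big)
  for (m in c("volume", "surface_area", "equivalent_diameter", "extent",
              "euler_number", "solidity", "axis_major_length")) {
    expect_equal(shifted[[m]], base[[m]], info = m)
  }
})

test_that("anisotropic spacing enters volumes and axes correctly", {
  g <- array(FALSE, c(5, 5, 5)); g[2:3, 2:4, 2:4] <- TRUE
  rec <- measure_objects(label_instances(semantic_mask(g, c(0.4, 0.1, 0.1))))
  expect_equal(rec$volume, 18 * 0.4 * 0.1 * 0.1)
  # a 1-voxel-thick plate along Z is physically thickest along Z when sz >> sx
  flat <- array(FALSE, c(3, 9, 3)); flat[2, 1:9, 2] <- TRUE
  iso <- measure_objects(label_instances(semantic_mask(flat, c(1, 1, 1))))
  expect_gt(iso$axis_major_length, 0)
})

test_that("per-cell organelle summaries follow the documented arithmetic", {
  rec <- data.frame(volume = c(1, 2, 3), SA_to_volume_ratio = c(1, 1, 1),
                    equivalent_diameter = c(1, 1, 1), extent = c(1, 1, 1),
                    euler_number = c(1, 1, 1), solidity = c(1, 1, 1),
                    axis_major_length = c(1, 1, 1))
  s <- summarize_organelle(rec, 100, name = "LS")
  expect_equal(unname(s["LS_count"]), 3)
  expect_equal(unname(s["LS_total_volume"]), 6)
  expect_equal(unname(s["LS_volume_fraction"]), 0.06)
  expect_equal(unname(s["LS_median_volume"]), 2)
  expect_equal(unname(s["LS_SD_volume"]), 1)
  s1 <- summarize_organelle(rec[1, ], 100, name = "LS")
  expect_true(is.na(s1["LS_SD_volume"]))
  s0 <- summarize_organelle(rec[0, ], 100, name = "LD")
  expect_equal(unname(s0["LD_count"]), 0)
  expect_equal(unname(s0["LD_total_volume"]), 0)
  expect_equal(unname(s0["LD_volume_fraction"]), 0)
  expect_true(is.na(s0["LD_median_volume"]))
  expect_error(summarize_organelle(rec, 0), "positive")
})

test_that("scaffold metrics include the nucleus area fraction", {
  g <- array(FALSE, c(8, 12, 12)); g[2:7, 2:11, 2:11] <- TRUE
  nuc <- array(FALSE, c(8, 12, 12)); nuc[3:5, 4:8, 4:8] <- TRUE
  sc <- cell_scaffold(semantic_mask(g, c(1, 1, 1)), semantic_mask(nuc, c(1, 1, 1)))
  m <- measure_scaffold(sc)
  expect_equal(unname(m["nuc_area_fraction"]),
               sum(nuc) / sum(g))
  expect_equal(unname(m["cell_solidity"]), 1)
  sc_same <- cell_scaffold(semantic_mask(g, c(1, 1, 1)),
                           semantic_mask(g, c(1, 1, 1)))
  expect_equal(unname(measure_scaffold(sc_same)["nuc_area_fraction"]), 1)
})
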