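small_params <- function() scaffold_params(dim = c(10, 40, 40),
                                            spacing = c(0.41, 0.16, 0.16))

test_that("phantom generation is seed-deterministic", {
  specs <- list(organelle_spec("LS", count = 5, radius_um = 0.3))
  a <- generate_cell(specs, scaffold = small_params(), seed = 4)
  b <- generate_cell(specs, scaffold = small_params(), seed = 4)
  expect_identical(a$image$organelles$LS$grid, b$image$organelles$LS$grid)
  expect_identical(a$image$scaffold$cell$grid, b$image$scaffold$cell$grid)
  c2 <- generate_cell(specs, scaffold = small_params(), seed = 5)
  expect_false(identical(a$image$organelles$LS$grid,
                         c2$image$organelles$LS$grid))
})

test_that("ground-truth counts equal instancing counts for disjoint placement", {
  for (s in 1:8) {
    specs <- list(organelle_spec("LS", count = 5, radius_um = 0.30),
                  organelle_spec("PO", count = 4, radius_um = 0.20))
    res <- generate_cell(specs, scaffold = small_params(), seed = s)
    for (org in c("LS", "PO")) {
      lab <- label_instances(res$image$organelles[[org]])
      expect_equal(lab$n_labels, res$truth$organelles[[org]]$count)
    }
    # organelle foreground stays inside the cell and out of the nucleus
    for (org in c("LS", "PO")) {
      g <- res$image$organelles[[org]]$grid
      expect_false(any(g & !res$image$scaffold$cell$grid))
      expect_false(any(g & res$image$scaffold$nucleus$grid))
    }
  }
})

test_that("zero-count channels come back empty with zero ground truth", {
  specs <- list(organelle_spec("LD", count = 0))
  res <- generate_cell(specs, scaffold = small_params(), seed = 2)
  expect_false(any(res$image$organelles$LD$grid))
  expect_equal(res$truth$organelles$LD$count, 0)
})

test_that("impossible placement requests fail with an explicit error", {
  specs <- list(organelle_spec("LS", count = 500, radius_um = 0.9))
  expect_error(generate_cell(specs, scaffold = small_params(), seed = 1,
                             max_attempts = 50),
               "infeasible-placement.*LS")
})

test_that("presets differ in their documented planted parameters", {
  n <- phantom_preset("neuron_like")
  a <- phantom_preset("astrocyte_like")
  get <- function(p, org) p$specs[[which(vapply(p$specs, `[[`, "", "name") == org)]]
  expect_gt(mean(get(n, "MT")$count), mean(get(a, "MT")$count))
  # astrocyte lysosomes: more objects, larger, strongly perinuclear
  expect_gt(mean(get(a, "LS")$count), mean(get(n, "LS")$count))
  expect_gt(get(a, "LS")$radius_um, get(n, "LS")$radius_um)
  bias_mean <- function(b) b[1] / (b[1] + b[2])
  expect_lt(bias_mean(get(a, "LS")$radial_bias),
            bias_mean(get(n, "LS")$radial_bias))
  rate_of <- function(p, x, y) {
    i <- Filter(function(s) s$a == x && s$b == y, p$interactions)[[1]]
    i$rate
  }
  expect_gt(rate_of(n, "MT", "ER"), rate_of(a, "MT", "ER"))
  expect_gt(rate_of(a, "PO", "LS"), rate_of(n, "PO", "LS"))
  expect_error(phantom_preset("glia_like"), "unknown preset")
})

test_that("planted overlap rates are recovered within sampling error", {
  rate <- 0.5
  measured <- planted <- numeric(0)
  n_a_total <- 0
  for (s in 1:50) {
    specs <- list(organelle_spec("LS", count = 3, radius_um = 0.35),
                  organelle_spec("PO", count = 8, radius_um = 0.20))
    inter <- list(interaction_spec("PO", "LS", rate = rate, depth = 1))
    res <- generate_cell(specs, inter, small_params(), seed = 600 + s)
    A <- label_instances(res$image$organelles$PO, channel = "PO")
    B <- label_instances(res$image$organelles$LS, channel = "LS")
    st <- find_sites(A, B)
    summ <- summarize_interaction(st, A, B)
    measured <- c(measured, summ[["PO-LS_percent_PO_involved"]])
    planted <- c(planted, res$truth$organelles$PO$planted_overlaps)
    n_a_total <- n_a_total + res$truth$organelles$PO$count
  }
  # measured involvement >= planted (chance overlaps can only add)
  expect_gte(mean(measured), 100 * sum(planted) / n_a_total - 1e-9)
  se <- 100 * sqrt(rate * (1 - rate) / n_a_total)
  expect_lt(abs(mean(measured) - 100 * rate), 3 * se + 10)
})

test_that("strong perinuclear bias puts the XY mode in ring 1 for nearly all seeds", {
  hits <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    specs <- list(organelle_spec("LS", count = 12, radius_um = 0.3,
                                 radial_bias = c(0.5, 8)))
    res <- generate_cell(specs, scaffold = small_params(), seed = 700 + s)
    xy <- build_xy_regions(res$image$scaffold)
    p <- profile_regions(res$image$organelles$LS, xy)
    if (which.max(p$n) == 1) hits <- hits + 1
  }
  expect_gte(hits, 0.9 * n_seeds)
})

test_that("track generator satisfies its kinematic contracts", {
  tr <- generate_tracks(1, "directed", speed_um_s = 0.2, frames = 60,
                        interval_s = 5, seed = 1)[[1]]
  s <- summarize_track(tr)
  expect_equal(unname(s["displacement"]), unname(s["total_distance"]))
  expect_equal(unname(s["displacement"]), 59)
  expect_equal(unname(s["median_speed"]), 0.2)
  expect_equal(unname(s["tortuosity"]), 1)
  st <- generate_tracks(1, "stationary", frames = 10, seed = 1)[[1]]
  ss <- summarize_track(st)
  expect_equal(unname(ss["displacement"]), 0)
  expect_equal(unname(ss["total_distance"]), 0)
  expect_true(is.na(ss["tortuosity"]))
  d1 <- generate_tracks(3, "diffusive", frames = 30, seed = 9)
  d2 <- generate_tracks(3, "diffusive", frames = 30, seed = 9)
  expect_identical(d1, d2)
  expect_error(generate_tracks(1, "directed", frames = 1), "frames")
})
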