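cell_fixture <- local({
  res <- NULL
  function() {
    if (is.null(res)) res <<- make_small_cell(seed = 11)
    res
  }
})

test_that("curated enumeration has the documented block sizes", {
  expect_length(curated_metric_names("morphology"), 65)
  expect_length(curated_metric_names("interaction"), 60)
  expect_length(curated_metric_names("distribution"), 109)
  expect_length(curated_metric_names(), 234)
  expect_false("ER_count" %in% curated_metric_names())
  expect_true("LS_total_volume" %in% curated_metric_names())
  expect_true("ER-MT_site_count" %in% curated_metric_names())
  expect_true("PO_XY_mode" %in% curated_metric_names())
})

test_that("a complete cell yields a 234-column curated row that is a subset of the full panel", {
  q <- quantify_cell(cell_fixture()$image)
  cur <- curate_signature(q$row)
  expect_length(cur, 234)
  expect_identical(names(cur), curated_metric_names())
  expect_equal(unname(cur), unname(q$row[names(cur)]))
  # all 15 pair summaries are present in the full row
  expect_true(all(paste0(ORGANELLE_PAIRS, "_site_count") %in% names(q$row)))
  # percent-involved and per-region normalized volumes live in the full panel
  expect_true("LS-PO_percent_PO_involved" %in% names(q$row))
  expect_true(all(paste0("LS_XY_n", 1:5) %in% names(q$row)))
  expect_false("LS_XY_n1" %in% names(cur))
})

test_that("quantification is deterministic and absent organelles degrade gracefully", {
  res <- cell_fixture()
  r1 <- quantify_cell(res$image)$row
  r2 <- quantify_cell(res$image)$row
  expect_identical(r1, r2)
  # remove all LD voxels
  img <- res$image
  dm <- dim(img$scaffold$cell$grid)
  img$organelles$LD <- semantic_mask(array(FALSE, dm), img$spacing)
  row <- quantify_cell(img)$row
  expect_equal(unname(row["LD_count"]), 0)
  expect_equal(unname(row["LD_total_volume"]), 0)
  expect_true(is.na(row["LD_median_volume"]))
  expect_true(is.na(row["LD_XY_mode"]))
  cur <- curate_signature(row)
  expect_length(cur, 234)
})

test_that("curation errors when a required column is missing", {
  q <- quantify_cell(cell_fixture()$image)
  row <- q$row[setdiff(names(q$row), "LS_total_volume")]
  expect_error(curate_signature(row), "LS_total_volume")
})

test_that("batch_combine keeps stable order and rejects mismatched columns", {
  r1 <- c(a = 1, b = 2); r2 <- c(a = 3, b = 4); r3 <- c(a = 5, b = 6)
  tab <- batch_combine(list(r1, r2, r3), group = c("g1", "g1", "g2"),
                       replicate = c("r1", "r2", "r1"))
  expect_equal(nrow(tab), 3)
  expect_identical(names(tab), c("cell_id", "group", "replicate", "a", "b"))
  expect_equal(tab$a, c(1, 3, 5))
  bad <- c(a = 1, c = 2)
  expect_error(batch_combine(list(r1, bad), group = c("g1", "g2")),
               "column mismatch")
})

test_that("signature tables round-trip through CSV bitwise", {
  q <- quantify_cell(cell_fixture()$image)
  tab <- batch_combine(list(q$row, q$row * 1), group = c("a", "b"))
  f <- tempfile(fileext = ".csv")
  write_signature(tab, f)
  back <- read_signature(f)
  expect_identical(names(back), names(tab))
  for (cn in metric_cols <- setdiff(names(tab), c("cell_id", "group", "replicate"))) {
    expect_identical(back[[cn]], tab[[cn]])
  }
})
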