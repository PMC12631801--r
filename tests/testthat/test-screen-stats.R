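test_that("Mann-Whitney p-values match exact enumeration for small groups", {
  # canonical fully-separated case: U = 0, exact two-sided p = 0.1
  tab <- data.frame(group = rep(c("A", "B"), each = 3),
                    m = c(1, 2, 3, 10, 11, 12))
  scr <- mwu_screen(tab, "A", "B")
  expect_equal(scr$U, 0)
  expect_equal(scr$p, 0.1)
  expect_equal(scr$mean_rank_diff, -3)
  # random tie-free cases, all group sizes up to 5
  set.seed(42)
  for (i in 1:12) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    xa <- runif(na); xb <- runif(nb) + runif(1, -0.5, 0.5)
    tt <- data.frame(group = rep(c("A", "B"), c(na, nb)), m = c(xa, xb))
    scr <- mwu_screen(tt, "A", "B")
    expect_equal(scr$p, oracle_mwu_p(xa, xb), tolerance = 1e-12)
  }
})

test_that("identical groups are never significant", {
  x <- c(1, 1, 2, 3, 3)
  tab <- data.frame(group = rep(c("A", "B"), each = 5), m = c(x, x))
  scr <- mwu_screen(tab, "A", "B")
  expect_gt(scr$p, 0.9)
  expect_false(scr$significant)
})

test_that("metrics with one or fewer data points per group are excluded", {
  tab <- data.frame(group = rep(c("A", "B"), each = 3),
                    good = c(1, 2, 3, 4, 5, 6),
                    sparse = c(1, NA, NA, 2, 3, 4))
  scr <- mwu_screen(tab, "A", "B")
  expect_identical(scr$metric, "good")
})

test_that("the two-stage BKY procedure matches hand-executed examples", {
  r <- bky_adjust(rep(1, 5), q = 0.1)
  expect_false(any(r$reject))
  # hand-worked: stage 1 at q' = 1/11 rejects {0.001, 0.002}; stage 2 at
  # q' * 4/2 rejects the same two
  r2 <- bky_adjust(c(0.001, 0.002, 0.9, 0.95), q = 0.1)
  expect_identical(r2$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$r1, 2L)
  r3 <- bky_adjust(rep(1e-9, 20), q = 0.1)
  expect_true(all(r3$reject))
  expect_error(bky_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BKY stage structure: rejections contain the BH set at q'", {
  set.seed(99)
  for (i in 1:20) {
    m <- sample(5:60, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- 0.1
    r <- bky_adjust(p, q)
    bh1 <- bh_reject(p, q / (1 + q))
    expect_true(all(r$reject[bh1]))       # stage 2 can only add rejections
    if (r$r1 == 0) expect_identical(r$reject, bh1)  # degenerates to BH at q'
    # q-value decisions are consistent with the rejection set
    expect_identical(r$reject, r$q_value <= q)
  }
})

test_that("BKY controls the empirical FDR on uniform p-values", {
  set.seed(7)
  reps <- 500; m <- 200
  fdp <- numeric(reps)
  for (i in seq_len(reps)) {
    r <- bky_adjust(runif(m), q = 0.1)
    # every rejection is false under the global null, so FDP is 1{R > 0}
    fdp[i] <- as.numeric(any(r$reject))
  }
  # under the global null, FDR = P(any rejection) <= q
  expect_lte(mean(fdp), 0.1 + 3 * sqrt(0.1 * 0.9 / reps))
})

test_that("log2 fold change handles degenerate means", {
  expect_equal(unname(log2_fc(c(8, 8), c(2, 2))), 2)
  expect_equal(unname(log2_fc(c(3, 5), c(3, 5))), 0)
  expect_true(is.na(log2_fc(c(1, 2), c(0, 0))))
})

test_that("significance tiers follow the q-value thresholds", {
  expect_identical(orgsig:::significance_tier(c(0.2, 0.09, 0.04, 0.009, 0.0009)),
                   c("ns", "*", "**", "***", "****"))
})

test_that("parallel-analysis PCA finds planted structure and ignores constants", {
  set.seed(1)
  n <- 20; p <- 12
  shift <- rep(c(0, 6), each = n / 2)
  x <- matrix(rnorm(n * p), n, p) + shift
  tab <- data.frame(group = rep(c("a", "b"), each = n / 2), x,
                    check.names = FALSE)
  res <- pca_parallel(tab, n_sim = 200, seed = 3)
  expect_gte(res$n_retained, 1)
  pc1 <- res$scores[, 1]
  expect_true(max(pc1[1:10]) < min(pc1[11:20]) ||
                min(pc1[1:10]) > max(pc1[11:20]))
  # constant column: dropped, scores unchanged
  tab2 <- tab
  tab2$const <- 5
  res2 <- pca_parallel(tab2, n_sim = 200, seed = 3)
  expect_true("const" %in% res2$dropped)
  expect_equal(res2$scores, res$scores)
  expect_error(pca_parallel(tab[1:2, ], n_sim = 10), "at least 3")
})

test_that("Ward clustering merges duplicates first and splits planted groups last", {
  x <- matrix(rnorm(8 * 5), 8, 5)
  x[2, ] <- x[1, ]                      # duplicate pair
  x[5:8, ] <- x[5:8, ] + 10             # planted second group
  tab <- data.frame(cell_id = paste0("c", 1:8), group = "g", x,
                    check.names = FALSE)
  hc <- hier_cluster(tab)
  expect_equal(min(hc$height), 0)
  first_merge <- hc$merge[1, ]
  expect_setequal(-first_merge, c(1, 2))
  top <- cutree(hc, k = 2)
  expect_equal(length(unique(top[1:4])), 1)
  expect_equal(length(unique(top[5:8])), 1)
  expect_false(top[1] == top[5])
})

test_that("Spearman correlation recovers monotone relations", {
  x <- data.frame(a = 1:20)
  y <- data.frame(up = (1:20)^2, down = -(1:20), noise = rnorm(20))
  sm <- spearman_matrix(x, y)
  expect_equal(unname(sm$r["a", "up"]), 1)
  expect_equal(unname(sm$r["a", "down"]), -1)
  expect_lt(abs(sm$r["a", "noise"]), 0.6)
  expect_error(spearman_matrix(x, y[1:5, , drop = FALSE]), "same number")
})
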