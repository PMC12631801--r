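# The statistical screen: per-metric Mann-Whitney U tests with two-stage
# Benjamini-Krieger-Yekutieli FDR control at 10%, log2 fold changes,
# standardized PCA with parallel-analysis component retention, Ward
# clustering, and Spearman correlation.

#' Two-stage Benjamini-Krieger-Yekutieli FDR procedure
#'
#' Linear step-up at q' = q/(1+q) (stage 1, yielding r1 rejections); if r1 is
#' 0 or m the procedure stops with that decision, otherwise a second linear
#' step-up is run at level q' * m / (m - r1). Reported q-values are the
#' smallest nominal q at which the metric is rejected in the second stage
#' with r1 held at its stage-1 value (monotone step-up adjustment).
#'
#' @param p numeric p-values between 0 and 1 (NA allowed; NA propagates).
#' @param q target false discovery rate (default 0.10).
#' @return A list: `reject` (logical), `q_value` (adjusted values), `r1`
#'   (stage-1 rejection count).
#' @export
bky_adjust <- function(p, q = 0.10) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]",
                                             call. = FALSE)
  ok <- !is.na(p)
  m <- sum(ok)
  reject <- rep(NA, length(p))
  qv <- rep(NA_real_, length(p))
  if (m == 0) return(list(reject = reject, q_value = qv, r1 = 0L))
  ps <- p[ok]
  qp <- q / (1 + q)
  step_up <- function(pv, level) {
    o <- order(pv)
    thr <- level * seq_along(pv) / length(pv)
    below <- pv[o] <= thr
    r <- if (any(below)) max(which(below)) else 0L
    rej <- logical(length(pv))
    if (r > 0) rej[o[seq_len(r)]] <- TRUE
    rej
  }
  r1 <- sum(step_up(ps, qp))
  if (r1 == 0L) {
    reject[ok] <- FALSE
    qv[ok] <- 1
    return(list(reject = reject, q_value = qv, r1 = 0L))
  }
  if (r1 == m) {
    rej2 <- rep(TRUE, m)
  } else {
    rej2 <- step_up(ps, qp * m / (m - r1))
  }
  # adjusted q-values: invert p <= i*q/((1+q)*m0) with m0 = m - r1
  m0 <- if (r1 == m) 1L else m - r1
  o <- order(ps)
  t_i <- ps[o] * m0 / seq_along(ps)
  t_i <- rev(cummin(rev(t_i)))          # enforce step-up monotonicity
  qq <- ifelse(t_i < 1, t_i / (1 - t_i), Inf)
  qvals <- numeric(m)
  qvals[o] <- pmin(qq, 1)
  reject[ok] <- rej2
  qv[ok] <- qvals
  list(reject = reject, q_value = qv, r1 = as.integer(r1))
}

significance_tier <- function(q_value) {
  ifelse(is.na(q_value), NA_character_,
         ifelse(q_value <= 0.001, "****",
                ifelse(q_value <= 0.01, "***",
                       ifelse(q_value <= 0.05, "**",
                              ifelse(q_value <= 0.1, "*", "ns")))))
}

#' Per-metric log2 fold change between group means
#'
#' log2(mean treated / mean control), defined only when both means are
#' strictly positive (missing otherwise).
#'
#' @param treated,control numeric matrices or data.frames (rows = cells,
#'   columns = shared metrics), or numeric vectors for a single metric.
#' @return Named numeric vector of log2 fold changes.
#' @export
log2_fc <- function(treated, control) {
  if (is.vector(treated)) treated <- matrix(treated, ncol = 1)
  if (is.vector(control)) control <- matrix(control, ncol = 1)
  mt <- colMeans(as.matrix(treated), na.rm = TRUE)
  mc <- colMeans(as.matrix(control), na.rm = TRUE)
  ifelse(is.finite(mt) & is.finite(mc) & mt > 0 & mc > 0,
         log2(mt / mc), NA_real_)
}

#' Mann-Whitney U screen between two groups of a signature table
#'
#' For every metric column: two-sided Mann-Whitney U test of group A vs
#' group B (exact distribution when both groups have at most 8 observations
#' and no ties, normal approximation with tie correction otherwise), with
#' pairwise deletion of missing values; metrics where either group retains
#' one or fewer data points are excluded. Multiplicity is handled by
#' [bky_adjust()] at the given FDR, with significance tiers
#' q <= 0.1 (*), 0.05 (**), 0.01 (***), 0.001 (****). The mean rank
#' difference (mean rank of A minus mean rank of B under joint ranking) and
#' the log2 fold change of group means are reported per metric.
#'
#' @param table signature table from [batch_combine()] (or any data.frame
#'   with a `group` column and numeric metric columns).
#' @param group_a,group_b the two group labels to compare (A vs B).
#' @param fdr target FDR for the BKY procedure (default 0.10).
#' @return A data.frame of class `screen_result`, one row per tested metric:
#'   n_a, n_b, U, p, q_value, significant, tier, mean_rank_diff, log2_fc.
#' @export
mwu_screen <- function(table, group_a, group_b, fdr = 0.10) {
  stopifnot(is.data.frame(table), "group" %in% names(table))
  a_rows <- table$group == group_a
  b_rows <- table$group == group_b
  if (!any(a_rows) || !any(b_rows)) {
    stop("empty group(s): ", if (!any(a_rows)) group_a else group_b,
         call. = FALSE)
  }
  metrics <- metric_columns(table)
  res <- lapply(metrics, function(mcol) {
    xa <- table[[mcol]][a_rows]
    xb <- table[[mcol]][b_rows]
    xa <- xa[!is.na(xa)]
    xb <- xb[!is.na(xb)]
    na <- length(xa); nb <- length(xb)
    if (na <= 1 || nb <= 1) return(NULL)
    ties <- anyDuplicated(c(xa, xb)) > 0
    exact <- (na <= 8 && nb <= 8 && !ties)
    wt <- suppressWarnings(wilcox.test(xa, xb, exact = exact, correct = !exact))
    if (is.na(wt$p.value)) wt$p.value <- 1  # fully tied groups
    ranks <- rank(c(xa, xb))
    mrd <- mean(ranks[seq_len(na)]) - mean(ranks[na + seq_len(nb)])
    data.frame(metric = mcol, n_a = na, n_b = nb,
               U = unname(wt$statistic), p = wt$p.value,
               mean_rank_diff = mrd,
               log2_fc = unname(log2_fc(xa, xb)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || nrow(res) == 0) {
    stop("no metric had at least two data points per group", call. = FALSE)
  }
  adj <- bky_adjust(res$p, q = fdr)
  res$q_value <- adj$q_value
  res$significant <- adj$reject
  res$tier <- significance_tier(res$q_value)
  res <- res[, c("metric", "n_a", "n_b", "U", "p", "q_value", "significant",
                 "tier", "mean_rank_diff", "log2_fc")]
  rownames(res) <- NULL
  class(res) <- c("screen_result", "data.frame")
  attr(res, "fdr") <- fdr
  attr(res, "groups") <- c(group_a, group_b)
  res
}

# z-score the metric columns, dropping zero-variance columns and columns
# with missing values (metrics undefined for cells lacking the phenotype);
# PCA and clustering need a complete matrix
standardize_table <- function(table) {
  metrics <- metric_columns(table)
  x <- as.matrix(table[, metrics, drop = FALSE])
  sds <- apply(x, 2, sd)
  drop <- names(sds)[is.na(sds) | sds == 0 | colSums(is.na(x)) > 0]
  keep <- setdiff(metrics, drop)
  x <- x[, keep, drop = FALSE]
  list(z = scale(x), dropped = drop, rows = seq_len(nrow(x)), kept = keep)
}

#' Standardized PCA with parallel-analysis component retention
#'
#' Metric columns are z-scored after dropping zero-variance columns; the PCA
#' eigenvalues are compared rank-by-rank against the given percentile of
#' eigenvalues from `n_sim` standard-normal matrices of identical shape
#' (each standardized the same way), and the leading run of components whose
#' observed eigenvalue exceeds its simulated percentile is retained.
#'
#' @param table signature table (data.frame with metric columns).
#' @param n_sim number of Monte Carlo simulations (default 1000).
#' @param percentile eigenvalue percentile for retention (default 95).
#' @param seed integer seed for the simulations.
#' @return A list of class `pca_result`: `n_retained`, `scores`, `loadings`,
#'   `var_explained` (percent), `eigenvalues`, `null_quantiles`, `dropped`,
#'   `rows`, `seed`.
#' @export
pca_parallel <- function(table, n_sim = 1000, percentile = 95, seed = 1) {
  std <- standardize_table(table)
  z <- std$z
  if (nrow(z) < 3) stop("need at least 3 complete rows for PCA", call. = FALSE)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  set.seed(seed)
  nulls <- matrix(NA_real_, n_sim, length(ev))
  for (s in seq_len(n_sim)) {
    zn <- scale(matrix(rnorm(nrow(z) * ncol(z)), nrow(z), ncol(z)))
    evn <- prcomp(zn, center = FALSE, scale. = FALSE)$sdev^2
    nulls[s, ] <- evn[seq_along(ev)]
  }
  thr <- apply(nulls, 2, quantile, probs = percentile / 100, na.rm = TRUE)
  above <- ev > thr
  n_ret <- if (above[1]) {
    runs <- rle(above)
    runs$lengths[1]
  } else 0L
  structure(list(n_retained = as.integer(n_ret),
                 scores = pc$x, loadings = pc$rotation,
                 var_explained = 100 * ev / sum(ev),
                 eigenvalues = ev, null_quantiles = thr,
                 dropped = std$dropped, rows = std$rows, seed = seed),
            class = "pca_result")
}

#' Ward hierarchical clustering of cells
#'
#' Ward ("ward.D") linkage on Euclidean distances between the standardized
#' metric rows (same preprocessing as [pca_parallel()]).
#'
#' @param table signature table.
#' @return The `hclust` object (leaf order is deterministic), with the
#'   standardized row indices as labels.
#' @export
hier_cluster <- function(table) {
  std <- standardize_table(table)
  if (nrow(std$z) < 2) stop("need at least 2 rows to cluster", call. = FALSE)
  labs <- if ("cell_id" %in% names(table)) table$cell_id[std$rows] else
    as.character(std$rows)
  d <- dist(std$z, method = "euclidean")
  hc <- hclust(d, method = "ward.D")
  hc$labels <- labs
  hc
}

#' Spearman correlation matrix between two sets of metrics
#'
#' Rank correlation (with average-rank tie handling) and two-sided p-value
#' for every column pair of `x` and `y`, rows paired.
#'
#' @param x,y data.frames or matrices with equal row counts.
#' @return A list with matrices `r` and `p` (rows = columns of x, columns =
#'   columns of y).
#' @export
spearman_matrix <- function(x, y) {
  x <- as.data.frame(x, check.names = FALSE)
  y <- as.data.frame(y, check.names = FALSE)
  if (nrow(x) != nrow(y)) stop("x and y must have the same number of rows",
                               call. = FALSE)
  r <- matrix(NA_real_, ncol(x), ncol(y),
              dimnames = list(names(x), names(y)))
  p <- r
  for (i in seq_len(ncol(x))) {
    for (j in seq_len(ncol(y))) {
      ok <- !is.na(x[[i]]) & !is.na(y[[j]])
      if (sum(ok) < 3) next
      ct <- suppressWarnings(cor.test(x[[i]][ok], y[[j]][ok],
                                      method = "spearman", exact = FALSE))
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  list(r = r, p = p)
}
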