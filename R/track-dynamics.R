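# Particle-track summary statistics from 2D time-lapse point tracks:
# displacement, total distance, and rolling-window (10-frame) speed and
# tortuosity summaries.

#' Summarise one track
#'
#' Displacement is the straight-line distance from the first to the last
#' point; total distance the sum of consecutive step lengths; speeds are
#' step length / frame interval. Rolling statistics are computed over all
#' 10-frame windows (stride 1): each window contributes its median speed,
#' SD of speeds, and tortuosity (window path length / window net
#' displacement, >= 1, missing for a window with zero net displacement);
#' windows are aggregated by the median. Tracks shorter than the window use
#' one whole-track window and are flagged.
#'
#' @param track data.frame with columns `frame`, `x`, `y` (micrometres) and
#'   strictly increasing frames; attribute `interval_s` or the argument
#'   gives the frame interval.
#' @param window rolling window length in frames (default 10).
#' @param interval_s frame interval in seconds (default from the track
#'   attribute, else 5).
#' @return Named numeric vector: displacement, total_distance,
#'   median_speed, SD_speed, tortuosity, short_track (0/1 flag).
#' @export
summarize_track <- function(track, window = 10, interval_s = NULL) {
  if (is.null(interval_s)) {
    interval_s <- attr(track, "interval_s")
    if (is.null(interval_s)) interval_s <- 5
  }
  n <- nrow(track)
  if (n < 2) stop("a track needs at least 2 points", call. = FALSE)
  if (any(diff(track$frame) <= 0)) {
    stop("frame indices must be strictly increasing", call. = FALSE)
  }
  dx <- diff(track$x); dy <- diff(track$y)
  steps <- sqrt(dx^2 + dy^2)
  disp <- sqrt((track$x[n] - track$x[1])^2 + (track$y[n] - track$y[1])^2)
  total <- sum(steps)
  speeds <- steps / interval_s
  short <- n < window
  win <- if (short) n else window
  starts <- seq_len(n - win + 1)
  med_sp <- sd_sp <- tor <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    s0 <- starts[i]
    idx <- s0:(s0 + win - 2)          # steps inside the window
    sp <- speeds[idx]
    med_sp[i] <- median(sp)
    sd_sp[i] <- if (length(sp) >= 2) sd(sp) else NA_real_
    net <- sqrt((track$x[s0 + win - 1] - track$x[s0])^2 +
                  (track$y[s0 + win - 1] - track$y[s0])^2)
    tor[i] <- if (net > 0) sum(steps[idx]) / net else NA_real_
  }
  c(displacement = disp, total_distance = total,
    median_speed = median(med_sp, na.rm = TRUE),
    SD_speed = if (all(is.na(sd_sp))) NA_real_ else median(sd_sp, na.rm = TRUE),
    tortuosity = if (all(is.na(tor))) NA_real_ else median(tor, na.rm = TRUE),
    short_track = as.numeric(short))
}

#' Summarise a list of tracks into a table
#'
#' @param tracks list of track data.frames (e.g. from [generate_tracks()] or
#'   [read_tracks()]).
#' @inheritParams summarize_track
#' @return data.frame with one row per track.
#' @export
summarize_tracks <- function(tracks, window = 10, interval_s = NULL) {
  rows <- lapply(tracks, summarize_track, window = window,
                 interval_s = interval_s)
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(track_id = vapply(tracks, function(t) t$track_id[1], 0), out)
  rownames(out) <- NULL
  out
}

#' Compare track summary metrics between two groups
#'
#' Runs the same Mann-Whitney U / BKY-FDR screen as the signature analysis
#' on the per-track summary metrics.
#'
#' @param summaries_a,summaries_b data.frames from [summarize_tracks()].
#' @param fdr target FDR (default 0.10).
#' @return A `screen_result` data.frame.
#' @export
compare_track_groups <- function(summaries_a, summaries_b, fdr = 0.10) {
  if (nrow(summaries_a) < 2 || nrow(summaries_b) < 2) {
    stop("need at least 2 tracks per group", call. = FALSE)
  }
  metrics <- c("displacement", "total_distance", "median_speed", "SD_speed",
               "tortuosity")
  tab <- rbind(
    data.frame(group = "A", summaries_a[, metrics], check.names = FALSE),
    data.frame(group = "B", summaries_b[, metrics], check.names = FALSE)
  )
  names(tab) <- c("group", metrics)
  mwu_screen(tab, "A", "B", fdr = fdr)
}
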