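#' Score immobility-defined sleep from a mobility trace
#'
#' Sleep is scored wherever the immobile-area fraction stays at or above
#' \code{threshold} for an uninterrupted run of at least \code{min_seconds}
#' (default: 95\% immobility sustained for 40 s, the video criterion
#' validated against EEG). Shorter immobile runs are wake. The per-second
#' flag is then aggregated onto ZT-aligned one-minute bins as seconds of
#' sleep per minute; partial leading/trailing minutes are dropped.
#'
#' @param trace a \code{\link{mobility_trace}} sampled at >= 1 Hz.
#' @param threshold immobility fraction defining stillness (default 0.95).
#' @param min_seconds minimum episode length in seconds (default 40).
#' @return an object of class \code{"sleep_series"}: list with \code{asleep}
#'   (per-sample logical), \code{sleep_seconds} (per ZT-aligned minute),
#'   \code{minute_zt_start} (ZT hours of the first minute bin),
#'   \code{schedule}, \code{threshold}, \code{min_seconds},
#'   \code{sample_seconds}.
#' @examples
#' tr <- mobility_trace(rep(c(1, 0), c(120, 120)))
#' sum(score_sleep(tr)$asleep)  # 120 s of sleep
#' @export
score_sleep <- function(trace, threshold = 0.95, min_seconds = 40) {
  stopifnot(inherits(trace, "mobility_trace"))
  if (trace$sample_seconds > 1)
    stop("trace must be sampled at >= 1 Hz")
  imm <- trace$immobility
  if (any(is.na(imm)))
    stop("immobility trace contains missing samples")
  min_samples <- ceiling(min_seconds / trace$sample_seconds)
  still <- imm >= threshold
  r <- rle(still)
  keep <- r$values & r$lengths >= min_samples
  asleep <- inverse.rle(list(lengths = r$lengths, values = keep))

  # ZT-aligned minute grid
  sec_per_sample <- trace$sample_seconds
  start_sec <- trace$start_time * 3600
  samp_start <- start_sec + (seq_along(imm) - 1) * sec_per_sample
  minute_id <- floor(samp_start / 60)
  n_samp <- rowsum(rep(1, length(minute_id)), minute_id)
  sums <- rowsum(as.numeric(asleep), minute_id)
  ids <- as.numeric(rownames(sums))
  full <- as.numeric(n_samp) * sec_per_sample >= 60 - 1e-9
  full_ids <- ids[full]
  sleep_sec <- as.numeric(sums[full]) * sec_per_sample
  structure(list(asleep = asleep,
                 sleep_seconds = sleep_sec,
                 minute_zt_start = full_ids[1] / 60,
                 schedule = trace$schedule,
                 threshold = threshold,
                 min_seconds = min_seconds,
                 sample_seconds = sec_per_sample),
            class = "sleep_series")
}

#' @export
print.sleep_series <- function(x, ...) {
  cat(sprintf("<sleep_series> %d min scored (threshold %g, min episode %g s)\n",
              length(x$sleep_seconds), x$threshold, x$min_seconds))
  cat(sprintf("  total sleep: %.1f min\n", sum(x$sleep_seconds) / 60))
  invisible(x)
}

# split the minute grid into complete days and label day (ZT 0-12) vs
# night (ZT 12-24) minutes
.sleep_day_grid <- function(series) {
  mins <- series$minute_zt_start * 60 + (seq_along(series$sleep_seconds) - 1)
  day_idx <- floor(mins / 1440)
  zt_min <- mins %% 1440
  complete <- as.numeric(names(which(table(day_idx) == 1440)))
  list(day_idx = day_idx, zt_min = zt_min, complete_days = complete)
}

#' Daily day/night sleep totals
#'
#' Minutes of sleep summed within the day window (ZT 0-12) and the night
#' window (ZT 12-24), per complete day, then averaged across days. Partial
#' days are excluded and flagged.
#'
#' @param series a \code{"sleep_series"} spanning at least one full day.
#' @return a \code{"sleep_metrics"} list with \code{day_sleep_min},
#'   \code{night_sleep_min} (cross-day means), \code{per_day} data frame,
#'   and \code{partial_days_excluded}.
#' @export
sleep_totals <- function(series) {
  stopifnot(inherits(series, "sleep_series"))
  g <- .sleep_day_grid(series)
  if (!length(g$complete_days))
    stop("sleep series does not span a full day on the ZT grid")
  rows <- lapply(g$complete_days, function(d) {
    sel <- g$day_idx == d
    ss <- series$sleep_seconds[sel]
    zt <- g$zt_min[sel]
    data.frame(day = d + 1,
               day_sleep_min = sum(ss[zt < 720]) / 60,
               night_sleep_min = sum(ss[zt >= 720]) / 60)
  })
  per_day <- do.call(rbind, rows)
  structure(list(day_sleep_min = mean(per_day$day_sleep_min),
                 night_sleep_min = mean(per_day$night_sleep_min),
                 per_day = per_day,
                 partial_days_excluded =
                   length(unique(g$day_idx)) - length(g$complete_days)),
            class = "sleep_metrics")
}

#' @export
print.sleep_metrics <- function(x, ...) {
  cat(sprintf("<sleep_metrics> day %.1f min, night %.1f min (mean over %d day(s))\n",
              x$day_sleep_min, x$night_sleep_min, nrow(x$per_day)))
  invisible(x)
}

#' Sleep bouts at one-minute resolution
#'
#' A sleep bout is a maximal run of consecutive minutes each containing at
#' least \code{min_sec_per_bin} seconds of sleep. Bouts are attributed
#' exclusively to the day (ZT 0-12) or night (ZT 12-24) window; a bout
#' spanning ZT 12 (or a day boundary) is split there so that day/night
#' accounting is exact. Counts and mean durations are averaged per day
#' within each window.
#'
#' @param series a \code{"sleep_series"}.
#' @param min_sec_per_bin seconds of sleep a minute needs to belong to a
#'   bout (default 40).
#' @return a \code{"sleep_bouts"} list: \code{bouts} data frame (\code{day},
#'   \code{window} "day"/"night", \code{start_zt_min}, \code{duration_min}),
#'   per-window per-day mean counts (\code{day_bouts}, \code{night_bouts})
#'   and mean durations in minutes (\code{day_mean_bout_min},
#'   \code{night_mean_bout_min}).
#' @export
sleep_bouts <- function(series, min_sec_per_bin = 40) {
  stopifnot(inherits(series, "sleep_series"))
  g <- .sleep_day_grid(series)
  if (!length(g$complete_days))
    stop("sleep series does not span a full day on the ZT grid")
  inbout <- series$sleep_seconds >= min_sec_per_bin
  # segment label: day index x half-day window; runs may not cross segments
  seg <- paste0(g$day_idx, "/", ifelse(g$zt_min < 720, "D", "N"))
  keep <- g$day_idx %in% g$complete_days
  bouts <- list()
  i <- 1L; n <- length(inbout)
  while (i <= n) {
    if (!inbout[i] || !keep[i]) { i <- i + 1L; next }
    j <- i
    while (j + 1L <= n && inbout[j + 1L] && keep[j + 1L] &&
           seg[j + 1L] == seg[i]) j <- j + 1L
    bouts[[length(bouts) + 1L]] <- data.frame(
      day = g$day_idx[i] + 1,
      window = ifelse(g$zt_min[i] < 720, "day", "night"),
      start_zt_min = g$zt_min[i],
      duration_min = j - i + 1L)
    i <- j + 1L
  }
  tbl <- if (length(bouts)) do.call(rbind, bouts) else
    data.frame(day = numeric(), window = character(),
               start_zt_min = numeric(), duration_min = numeric())
  nd <- length(g$complete_days)
  win_stats <- function(w) {
    sub <- tbl[tbl$window == w, , drop = FALSE]
    list(count = nrow(sub) / nd,
         mean_dur = if (nrow(sub)) mean(sub$duration_min) else 0)
  }
  dstat <- win_stats("day"); nstat <- win_stats("night")
  structure(list(bouts = tbl,
                 day_bouts = dstat$count, night_bouts = nstat$count,
                 day_mean_bout_min = dstat$mean_dur,
                 night_mean_bout_min = nstat$mean_dur,
                 n_days = nd),
            class = "sleep_bouts")
}

#' @export
print.sleep_bouts <- function(x, ...) {
  cat(sprintf("<sleep_bouts> day: %.1f bouts/day, mean %.1f min; night: %.1f bouts/day, mean %.1f min\n",
              x$day_bouts, x$day_mean_bout_min,
              x$night_bouts, x$night_mean_bout_min))
  invisible(x)
}

#' Distribution of daytime sleep-bout durations
#'
#' Histogram of daytime bout durations in classes of \code{interval_minutes}
#' (default 30 min), each class normalized by the total number of daytime
#' bouts. With \code{fine = TRUE}, restricts to bouts shorter than
#' \code{interval_minutes} and bins them at \code{fine_interval} minutes,
#' normalized by the same total.
#'
#' @param bouts a \code{"sleep_bouts"} object.
#' @param interval_minutes coarse class width (default 30).
#' @param fine if TRUE, the fine-resolution sub-30-min variant.
#' @param fine_interval class width of the fine variant (default 5).
#' @return data frame with \code{lower}, \code{upper} (minutes) and
#'   \code{fraction}; fractions of the coarse variant sum to 1.
#' @export
bout_duration_distribution <- function(bouts, interval_minutes = 30,
                                       fine = FALSE, fine_interval = 5) {
  stopifnot(inherits(bouts, "sleep_bouts"))
  dur <- bouts$bouts$duration_min[bouts$bouts$window == "day"]
  if (!length(dur)) {
    out <- data.frame(lower = numeric(), upper = numeric(),
                      fraction = numeric())
    attr(out, "empty") <- TRUE
    return(out)
  }
  total <- length(dur)
  if (fine) {
    dur <- dur[dur < interval_minutes]
    width <- fine_interval
    top <- interval_minutes
  } else {
    width <- interval_minutes
    top <- ceiling(max(dur) / width) * width
  }
  lower <- seq(0, top - width, by = width)
  frac <- vapply(lower, function(lo)
    sum(dur > lo & dur <= lo + width) / total, 0)
  # durations are >= 1 min so the (lo, lo+width] classes cover everything
  data.frame(lower = lower, upper = lower + width, fraction = frac)
}

#' Sensitivity of sleep metrics to the immobility threshold
#'
#' Rescores sleep at each threshold (default 90, 95, 97\% immobility) and
#' reports the full metric set per threshold plus the percentage change of
#' each metric relative to the reference threshold:
#' \eqn{\Delta\% = 100 (m(t) - m(ref)) / m(ref)}. Metrics that are zero at
#' the reference give \code{NA} deltas (flagged undefined).
#'
#' @param trace a \code{\link{mobility_trace}}.
#' @param thresholds immobility thresholds to evaluate
#'   (default \code{c(0.90, 0.95, 0.97)}).
#' @param reference threshold the deltas are computed against (default 0.95).
#' @param min_seconds minimum episode length in seconds (default 40).
#' @return a \code{"threshold_sensitivity"} list with \code{metrics}
#'   (data frame, one row per threshold) and \code{delta_pct} (data frame of
#'   percentage changes vs the reference).
#' @export
threshold_sensitivity <- function(trace, thresholds = c(0.90, 0.95, 0.97),
                                  reference = 0.95, min_seconds = 40) {
  stopifnot(inherits(trace, "mobility_trace"))
  if (!reference %in% thresholds) thresholds <- sort(c(thresholds, reference))
  rows <- lapply(thresholds, function(t) {
    ser <- score_sleep(trace, threshold = t, min_seconds = min_seconds)
    tot <- sleep_totals(ser)
    bts <- sleep_bouts(ser)
    data.frame(threshold = t,
               day_sleep_min = tot$day_sleep_min,
               night_sleep_min = tot$night_sleep_min,
               day_bouts = bts$day_bouts,
               night_bouts = bts$night_bouts,
               day_mean_bout_min = bts$day_mean_bout_min,
               night_mean_bout_min = bts$night_mean_bout_min)
  })
  metrics <- do.call(rbind, rows)
  ref_row <- metrics[metrics$threshold == reference, -1]
  delta <- lapply(seq_len(nrow(metrics)), function(i) {
    m <- metrics[i, -1]
    d <- 100 * (m - ref_row) / ref_row
    d[ref_row == 0] <- NA
    d
  })
  delta_pct <- cbind(threshold = metrics$threshold, do.call(rbind, delta))
  structure(list(metrics = metrics, delta_pct = delta_pct,
                 reference = reference),
            class = "threshold_sensitivity")
}

#' @export
print.threshold_sensitivity <- function(x, ...) {
  cat("<threshold_sensitivity> reference threshold:", x$reference, "\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
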