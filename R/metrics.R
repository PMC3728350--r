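#' Average daily waveform
#'
#' Per-bin mean and SEM across days of a folded record; gap bins are
#' excluded from the mean (never zero-filled).
#'
#' @param day_matrix a \code{"day_matrix"} from \code{\link{fold_days}}.
#' @return a \code{"daily_waveform"}: list with \code{mean}, \code{sem}
#'   (NA when a single day), \code{bin_minutes}.
#' @export
average_waveform <- function(day_matrix) {
  stopifnot(inherits(day_matrix, "day_matrix"))
  m <- unclass(day_matrix)
  mu <- apply(m, 2, mean, na.rm = TRUE)
  sem <- if (nrow(m) >= 2) {
    apply(m, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
    })
  } else rep(NA_real_, ncol(m))
  structure(list(mean = as.numeric(mu), sem = as.numeric(sem),
                 bin_minutes = attr(day_matrix, "bin_minutes")),
            class = "daily_waveform")
}

#' @export
print.daily_waveform <- function(x, ...) {
  cat(sprintf("<daily_waveform> %d bins of %g min; mean activity %.2f/bin\n",
              length(x$mean), x$bin_minutes, mean(x$mean, na.rm = TRUE)))
  invisible(x)
}

# shared helper: per-day percentage of counts inside an hour-of-day window set
.pct_in_window <- function(record, window_fn) {
  dm <- fold_days(record)
  m <- unclass(dm)
  bin_h <- attr(dm, "bin_minutes") / 60
  mid_h <- (seq_len(ncol(m)) - 0.5) * bin_h   # bin midpoints in ZT hours
  inw <- window_fn(mid_h)
  per_day <- apply(m, 1, function(row) {
    tot <- sum(row, na.rm = TRUE)
    if (tot <= 0) return(NA_real_)
    100 * sum(row[inw], na.rm = TRUE) / tot
  })
  excluded <- sum(is.na(per_day))
  val <- mean(per_day, na.rm = TRUE)
  if (is.nan(val)) stop("no day with positive total activity")
  attr(val, "days_excluded") <- excluded
  val
}

#' Nocturnality: percentage of activity in the dark
#'
#' Per-day percentage of counts falling in the schedule's dark window,
#' averaged over days. Days with zero total activity are excluded and
#' counted in the \code{days_excluded} attribute.
#'
#' @param record an \code{\link{activity_record}} under an LD or SKELETON
#'   schedule (a dark or subjective-night window must be defined).
#' @return percentage in [0, 100] with attribute \code{days_excluded}.
#' @export
nocturnality <- function(record) {
  stopifnot(inherits(record, "activity_record"))
  sched <- record$schedule
  .pct_in_window(record, function(h) in_dark(h, sched))
}

#' Mean activity amount in counts per hour
#'
#' Total counts divided by total recorded hours; gap bins contribute neither
#' counts nor time.
#'
#' @param record an \code{\link{activity_record}}.
#' @return revolutions (counts) per hour.
#' @export
activity_rate <- function(record) {
  stopifnot(inherits(record, "activity_record"))
  ok <- !is.na(record$counts)
  hours <- sum(ok) * record$bin_minutes / 60
  if (hours <= 0) stop("record contains no recorded bins")
  sum(record$counts[ok]) / hours
}

#' Alpha: duration of the daily active phase
#'
#' Threshold = mean of the average waveform; alpha is the longest
#' circularly-contiguous run of bins strictly above the threshold, in
#' minutes (the onset-to-offset span of the consolidated active phase).
#' A flat waveform with no bin above its mean gives alpha 0 and an
#' \code{"arrhythmic"} flag. Set \code{total = TRUE} to count total time
#' above threshold instead of the longest run.
#'
#' @param waveform a \code{"daily_waveform"} spanning 24 h.
#' @param total if TRUE, total suprathreshold time instead of longest run.
#' @return alpha in minutes (0 to 1440), with attribute \code{arrhythmic}.
#' @export
alpha_duration <- function(waveform, total = FALSE) {
  stopifnot(inherits(waveform, "daily_waveform"))
  v <- waveform$mean
  thr <- mean(v, na.rm = TRUE)
  above <- !is.na(v) & v > thr
  if (!any(above)) {
    out <- 0
    attr(out, "arrhythmic") <- TRUE
    return(out)
  }
  if (total) {
    out <- sum(above) * waveform$bin_minutes
  } else if (all(above)) {
    out <- length(above) * waveform$bin_minutes
  } else {
    # longest circular run: double the vector, cap runs at one cycle
    r <- rle(c(above, above))
    runs <- r$lengths[r$values]
    out <- min(max(runs), length(above)) * waveform$bin_minutes
  }
  attr(out, "arrhythmic") <- FALSE
  out
}

#' Daily activity-onset detection
#'
#' Per day, the onset is the start of the first bin \code{B} such that
#' (a) bins in the \code{quiet_hours} window before \code{B} are below the
#' threshold with at most one violating bin, and (b) at least
#' \code{active_frac} of the bins in the following \code{active_window_h}
#' (including \code{B}) are above threshold. The threshold is
#' \code{threshold_frac} times the day's mean positive-bin count. The quiet
#' window may look back across the day boundary into the previous day. Days
#' with no qualifying bin give \code{NA}.
#'
#' These parameters mimic onset pickers in actogram software; all four are
#' exposed so results can be matched to other tools.
#'
#' @param day_matrix a \code{"day_matrix"}.
#' @param threshold_frac threshold as a fraction of the daily mean positive
#'   bin count (default 0.2).
#' @param quiet_hours required preceding quiescence in hours (default 4).
#' @param active_frac required fraction of suprathreshold bins in the
#'   active window (default 0.5).
#' @param active_window_h forward confirmation window in hours (default 1).
#' @return numeric vector of onset times in minutes after ZT0 (0-1439),
#'   one per day, \code{NA} where undetected.
#' @export
detect_onsets <- function(day_matrix, threshold_frac = 0.2, quiet_hours = 4,
                          active_frac = 0.5, active_window_h = 1) {
  stopifnot(inherits(day_matrix, "day_matrix"))
  m <- unclass(day_matrix)
  bin_min <- attr(day_matrix, "bin_minutes")
  bpd <- ncol(m)
  x <- as.vector(t(m))                       # concatenated trimmed series
  quiet_bins <- as.integer(round(quiet_hours * 60 / bin_min))
  act_bins <- as.integer(round(active_window_h * 60 / bin_min))
  onsets <- rep(NA_real_, nrow(m))
  for (d in seq_len(nrow(m))) {
    day <- m[d, ]
    pos <- day[!is.na(day) & day > 0]
    if (!length(pos)) next
    thr <- threshold_frac * mean(pos)
    d0 <- (d - 1L) * bpd                     # offset of day d in x
    for (b in seq_len(bpd)) {
      i <- d0 + b                            # global index of candidate bin
      val <- x[i]
      if (is.na(val) || val <= thr) next
      # (a) quiet window before the candidate
      lo <- i - quiet_bins
      if (lo < 1) next                       # not enough history
      q <- x[lo:(i - 1L)]
      if (sum(!is.na(q) & q >= thr) > 1L) next
      # (b) forward activity confirmation
      hi <- min(i + act_bins - 1L, length(x))
      a <- x[i:hi]
      if (mean(!is.na(a) & a > thr) < active_frac) next
      onsets[d] <- (b - 1L) * bin_min
      break
    }
  }
  onsets
}

# unwrap onset minutes across the 24-h boundary so that successive onsets
# never jump by more than half a cycle (free-running drift becomes linear)
unwrap_onsets <- function(onsets) {
  out <- onsets
  idx <- which(!is.na(out))
  if (length(idx) < 2) return(out)
  offset <- 0
  for (k in 2:length(idx)) {
    i <- idx[k]; j <- idx[k - 1L]
    out[i] <- out[i] + offset
    adj <- -round((out[i] - out[j]) / 1440) * 1440
    out[i] <- out[i] + adj
    offset <- offset + adj
  }
  out
}

#' Onset precision: daily variation about a best-fit regression line
#'
#' Fits a least-squares line to onset minute versus day index (onsets
#' unwrapped across the 24-h boundary so a free-running drift is linear)
#' and reports the mean absolute residual in minutes. Zero means perfectly
#' collinear onsets. Reported as a magnitude; larger values mean a less
#' precise clock.
#'
#' @param onsets onset minutes per day, as from \code{\link{detect_onsets}};
#'   \code{NA} days are dropped. At least 3 onsets required.
#' @return mean absolute residual in minutes (>= 0).
#' @export
onset_precision <- function(onsets) {
  u <- unwrap_onsets(onsets)
  keep <- !is.na(u)
  if (sum(keep) < 3) stop("insufficient onsets: need at least 3")
  day <- seq_along(u)[keep]
  fit <- stats::lm(u[keep] ~ day)
  mean(abs(stats::residuals(fit)))
}

#' Activity-bout detection and fragmentation
#'
#' A bout opens at a bin whose count exceeds \code{count_threshold},
#' continues across sub-threshold gaps shorter than \code{max_gap_minutes},
#' and closes at the last suprathreshold bin before a gap of at least
#' \code{max_gap_minutes}. Bouts spanning less than \code{min_bout_minutes}
#' are discarded. Fragmentation is the mean number of bouts per day.
#'
#' @param record an \code{\link{activity_record}}.
#' @param count_threshold bins with counts strictly greater are active
#'   (default 0).
#' @param max_gap_minutes gap tolerance within a bout (default 21).
#' @param min_bout_minutes minimum bout span to keep (default 21).
#' @return a \code{"bout_table"}: data frame with \code{day} (1-based day of
#'   bout start), \code{start_minute}, \code{end_minute} (record-relative
#'   minutes, end exclusive), \code{duration_minutes}, \code{total_counts};
#'   attribute \code{bouts_per_day} = total bouts / days spanned.
#' @export
activity_bouts <- function(record, count_threshold = 0,
                           max_gap_minutes = 21, min_bout_minutes = 21) {
  stopifnot(inherits(record, "activity_record"))
  bin_min <- record$bin_minutes
  for (v in c(max_gap_minutes, min_bout_minutes)) {
    if (abs(v / bin_min - round(v / bin_min)) > 1e-9)
      stop("minute thresholds must be multiples of the bin width")
  }
  gap_bins <- as.integer(round(max_gap_minutes / bin_min))
  x <- record$counts
  active <- !is.na(x) & x > count_threshold
  bouts <- list()
  i <- 1L; n <- length(x)
  while (i <= n) {
    if (!active[i]) { i <- i + 1L; next }
    start <- i
    last_active <- i
    j <- i + 1L
    while (j <= n) {
      if (active[j]) {
        last_active <- j
        j <- j + 1L
      } else {
        # measure the run of inactive bins
        g <- 0L
        while (j + g <= n && !active[j + g]) g <- g + 1L
        if (g >= gap_bins || j + g > n) break
        j <- j + g
      }
    }
    span_bins <- last_active - start + 1L
    if (span_bins * bin_min >= min_bout_minutes) {
      bouts[[length(bouts) + 1L]] <- data.frame(
        day = ((start - 1L) * bin_min) %/% 1440 + 1L,
        start_minute = (start - 1L) * bin_min,
        end_minute = last_active * bin_min,
        duration_minutes = span_bins * bin_min,
        total_counts = sum(x[start:last_active], na.rm = TRUE))
    }
    i <- last_active + 1L
  }
  tbl <- if (length(bouts)) do.call(rbind, bouts) else
    data.frame(day = integer(), start_minute = numeric(),
               end_minute = numeric(), duration_minutes = numeric(),
               total_counts = numeric())
  ndays <- max(1, length(x) * bin_min / 1440)
  attr(tbl, "bouts_per_day") <- nrow(tbl) / ndays
  class(tbl) <- c("bout_table", "data.frame")
  tbl
}

#' All scalar circadian metrics for one record
#'
#' Convenience wrapper producing the standard per-animal row: nocturnality
#' (LD/skeleton only), rhythm power, activity amount, alpha, fragmentation,
#' onset precision, and tau.
#'
#' @param record an \code{\link{activity_record}}.
#' @param scan_h periodogram scan range in hours.
#' @param ... onset-detection parameters passed to
#'   \code{\link{detect_onsets}}.
#' @return a \code{"circadian_metrics"} one-row data frame.
#' @export
circadian_metrics <- function(record, scan_h = c(20, 28), ...) {
  stopifnot(inherits(record, "activity_record"))
  dm <- fold_days(record)
  wf <- average_waveform(dm)
  pg <- chisq_periodogram(record, scan_h[1], scan_h[2])
  ons <- detect_onsets(dm, ...)
  prec <- if (sum(!is.na(ons)) >= 3) onset_precision(ons) else NA_real_
  noct <- if (record$schedule$regime != "DD")
    as.numeric(nocturnality(record)) else NA_real_
  out <- data.frame(
    nocturnality_pct = noct,
    power_pct = pg$power_pct,
    activity_rev_per_hr = activity_rate(record),
    alpha_minutes = as.numeric(alpha_duration(wf)),
    fragmentation_bouts_per_day = attr(activity_bouts(record), "bouts_per_day"),
    precision_minutes = prec,
    tau_hours = pg$tau_hours)
  class(out) <- c("circadian_metrics", "data.frame")
  out
}
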