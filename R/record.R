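#' Binned locomotor-activity record
#'
#' A wheel-running (or other event-count) time series in fixed-width bins,
#' anchored to ZT0 of day 0. Missing bins are carried as \code{NA} and
#' excluded -- never zero-filled -- by every downstream metric.
#'
#' @param counts integer vector of non-negative counts per bin; \code{NA}
#'   marks a recording gap.
#' @param bin_minutes bin width in minutes (default 3); must divide 60.
#' @param start_time start of the first bin, in hours relative to ZT0 of
#'   day 0 (default 0).
#' @param schedule a \code{\link{light_schedule}}.
#' @return an object of class \code{"activity_record"}.
#' @examples
#' rec <- activity_record(rep(c(0L, 5L), each = 240), schedule = light_schedule("LD"))
#' rec
#' @export
activity_record <- function(counts, bin_minutes = 3, start_time = 0,
                            schedule = light_schedule("LD")) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (bin_minutes <= 0) stop("bin_minutes must be positive")
  if (abs(60 / bin_minutes - round(60 / bin_minutes)) > 1e-9)
    stop("bin_minutes must divide 60")
  counts <- as.numeric(counts)
  if (any(counts < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-9, na.rm = TRUE))
    stop("counts must be integers")
  structure(list(counts = as.integer(round(counts)),
                 bin_minutes = bin_minutes,
                 start_time = start_time,
                 schedule = schedule),
            class = "activity_record")
}

#' @export
print.activity_record <- function(x, ...) {
  n <- length(x$counts)
  cat(sprintf("<activity_record> %d bins of %g min (%.2f days), start ZT %g, %s\n",
              n, x$bin_minutes, n * x$bin_minutes / 1440,
              x$start_time %% 24, x$schedule$regime))
  ng <- sum(is.na(x$counts))
  if (ng) cat("  gaps:", ng, "bins\n")
  cat(sprintf("  total counts: %d, mean rate %.1f/hr\n",
              sum(x$counts, na.rm = TRUE),
              sum(x$counts, na.rm = TRUE) /
                (sum(!is.na(x$counts)) * x$bin_minutes / 60)))
  invisible(x)
}

#' Per-second mobility trace
#'
#' Fraction of the animal's area detected immobile in each video sample
#' (values in [0, 1]), the input to immobility-defined sleep scoring.
#'
#' @param immobility numeric vector of immobile-area fractions per sample.
#' @param sample_seconds sampling interval in seconds (default 1).
#' @param start_time start of the trace in hours relative to ZT0 (default 0).
#' @param schedule a \code{\link{light_schedule}}.
#' @return an object of class \code{"mobility_trace"}.
#' @export
mobility_trace <- function(immobility, sample_seconds = 1, start_time = 0,
                           schedule = light_schedule("LD")) {
  stopifnot(inherits(schedule, "light_schedule"))
  immobility <- as.numeric(immobility)
  if (any(immobility < 0 | immobility > 1, na.rm = TRUE))
    stop("immobility values must lie in [0, 1]")
  structure(list(immobility = immobility,
                 sample_seconds = sample_seconds,
                 start_time = start_time,
                 schedule = schedule),
            class = "mobility_trace")
}

#' @export
print.mobility_trace <- function(x, ...) {
  n <- length(x$immobility)
  cat(sprintf("<mobility_trace> %d samples at %g s (%.2f h), start ZT %g, %s\n",
              n, x$sample_seconds, n * x$sample_seconds / 3600,
              x$start_time %% 24, x$schedule$regime))
  invisible(x)
}

#' Read a binned activity record from a text file
#'
#' Accepts either a single column of counts per bin, or two comma-separated
#' columns (timestamp, count) where the timestamp column is ignored for
#' binning (bins are taken in file order). Blank fields and the sentinel
#' \code{NA} mark recording gaps; gaps are counted and reported via a
#' \code{"gaps"} attribute.
#'
#' @param path file to read.
#' @param bin_minutes bin width in minutes.
#' @param schedule a \code{\link{light_schedule}}.
#' @param start_time start of the first bin in hours relative to ZT0.
#' @return an \code{\link{activity_record}} with attribute \code{gaps} =
#'   number of missing bins.
#' @export
read_activity_csv <- function(path, bin_minutes = 3,
                              schedule = light_schedule("LD"),
                              start_time = 0) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  counts <- numeric(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    val <- trimws(fields[length(fields)])
    if (val == "" || toupper(val) == "NA") {
      counts[i] <- NA
      next
    }
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num))
      stop(sprintf("parse error at line %d: '%s'", i, lines[i]))
    if (num < 0)
      stop(sprintf("negative count at line %d: %s", i, val))
    counts[i] <- num
  }
  rec <- activity_record(counts, bin_minutes = bin_minutes,
                         start_time = start_time, schedule = schedule)
  attr(rec, "gaps") <- sum(is.na(counts))
  rec
}

#' Write an activity record as a single-column count file
#'
#' @param record an \code{\link{activity_record}}.
#' @param path file to write.
#' @return \code{path}, invisibly.
#' @export
write_activity_csv <- function(record, path) {
  stopifnot(inherits(record, "activity_record"))
  writeLines(ifelse(is.na(record$counts), "NA",
                    as.character(record$counts)), path)
  invisible(path)
}

#' Read a per-second immobility trace
#'
#' Single column of immobility fractions, one sample per line.
#'
#' @param path file to read.
#' @param sample_seconds sampling interval in seconds.
#' @param schedule a \code{\link{light_schedule}}.
#' @param start_time start of the trace in hours relative to ZT0.
#' @return a \code{\link{mobility_trace}}.
#' @export
read_mobility_csv <- function(path, sample_seconds = 1,
                              schedule = light_schedule("LD"),
                              start_time = 0) {
  vals <- scan(path, what = numeric(), sep = ",", quiet = TRUE)
  mobility_trace(vals, sample_seconds = sample_seconds,
                 start_time = start_time, schedule = schedule)
}

#' Fold an activity record into a day-by-bin matrix
#'
#' Trims any partial leading day (bins before the first ZT0 boundary) and
#' partial trailing day, then stacks complete 24-h days as rows. Days are
#' half-open \code{[ZT0, ZT0 + 24h)}; bin indices are ZT-aligned.
#'
#' @param record an \code{\link{activity_record}}.
#' @return a \code{"day_matrix"}: a numeric matrix (days x bins) with
#'   attributes \code{bin_minutes} and \code{schedule}.
#' @examples
#' rec <- activity_record(rep(1L, 4800))
#' dim(fold_days(rec))  # 10 days x 480 bins
#' @export
fold_days <- function(record) {
  stopifnot(inherits(record, "activity_record"))
  bpd <- as.integer(round(1440 / record$bin_minutes))
  # bins to skip before the first ZT0 boundary
  off_h <- record$start_time %% 24
  skip <- if (off_h == 0) 0L else {
    lead_h <- 24 - off_h
    lead_bins <- lead_h * 60 / record$bin_minutes
    if (abs(lead_bins - round(lead_bins)) > 1e-9)
      stop("start_time is not commensurate with the bin grid")
    as.integer(round(lead_bins))
  }
  usable <- length(record$counts) - skip
  ndays <- usable %/% bpd
  if (ndays < 1) stop("record does not cover one full day from a ZT0 boundary")
  kept <- record$counts[(skip + 1L):(skip + ndays * bpd)]
  m <- matrix(kept, nrow = ndays, ncol = bpd, byrow = TRUE)
  structure(m, bin_minutes = record$bin_minutes,
            schedule = record$schedule, class = c("day_matrix", "matrix"))
}

#' Resample an activity record to a coarser bin width
#'
#' Sums counts within the coarser bins; the total count is conserved exactly.
#' A bin containing any gap becomes a gap. Trailing bins that do not fill a
#' coarse bin are dropped.
#'
#' @param record an \code{\link{activity_record}}.
#' @param new_bin_minutes target bin width; must be an integer multiple of
#'   the current width.
#' @return an \code{\link{activity_record}} at the new bin width.
#' @export
resample_bins <- function(record, new_bin_minutes) {
  stopifnot(inherits(record, "activity_record"))
  f <- new_bin_minutes / record$bin_minutes
  if (abs(f - round(f)) > 1e-9 || f < 1)
    stop("new_bin_minutes must be an integer multiple of bin_minutes")
  f <- as.integer(round(f))
  if (f == 1L) return(record)
  n <- (length(record$counts) %/% f) * f
  x <- record$counts[seq_len(n)]
  grp <- rep(seq_len(n %/% f), each = f)
  sums <- tapply(x, grp, function(v) if (anyNA(v)) NA else sum(v))
  activity_record(as.vector(sums), bin_minutes = new_bin_minutes,
                  start_time = record$start_time, schedule = record$schedule)
}

#' Plot a double-plotted actogram
#'
#' Standard 48-h double plot: each row shows day d followed by day d + 1,
#' successive days from top to bottom.
#'
#' @param x an \code{\link{activity_record}}.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @return invisibly, the folded day matrix.
#' @export
plot.activity_record <- function(x, ...) {
  m <- fold_days(x)
  nd <- nrow(m); bpd <- ncol(m)
  op <- graphics::par(mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(0, 48), ylim = c(nd + 0.5, 0.5),
                 xlab = "Zeitgeber time (h, double-plotted)", ylab = "Day",
                 xaxs = "i", ...)
  mx <- max(m, 1, na.rm = TRUE)
  hrs <- (seq_len(bpd) - 1) * x$bin_minutes / 60
  for (d in seq_len(nd)) {
    row <- c(m[d, ], if (d < nd) m[d + 1L, ] else rep(NA, bpd))
    h <- c(hrs, hrs + 24)
    v <- pmin(row / mx, 1) * 0.9
    ok <- !is.na(row) & row > 0
    if (any(ok))
      graphics::segments(h[ok], d + 0.45, h[ok], d + 0.45 - v[ok], lwd = 1)
  }
  invisible(m)
}
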