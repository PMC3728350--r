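#' Phase-shift estimation from activity-onset regressions
#'
#' Aschoff type-II style estimate of the phase shift produced by a discrete
#' light pulse under constant darkness. Activity onsets are detected and
#' unwrapped, a least-squares line is fitted to the onsets of the
#' \code{pre_days} days up to and including the pulse day, and a second line
#' to \code{post_days} onsets beginning after \code{transient_days} days of
#' transients; both lines are extrapolated to the first post-pulse day and
#' the delay is their difference there. Positive values are phase delays
#' (onset moved later), negative values advances.
#'
#' @param record an \code{\link{activity_record}} in DD spanning the pulse.
#' @param pulse_day 1-based day (of the folded record) on which the pulse
#'   was given.
#' @param pre_days days fitted before the shift (default 7).
#' @param post_days days fitted after the transients (default 7).
#' @param transient_days post-pulse days excluded as transients (default 2).
#' @param min_fit_days minimum detected onsets required on each side
#'   (default 5).
#' @param ... onset-detection parameters for \code{\link{detect_onsets}}.
#' @return an object of class \code{"phase_shift"}: list with
#'   \code{delay_minutes}, \code{pre_fit}, \code{post_fit} (slope min/day,
#'   intercept min at day 0), \code{pulse_day},
#'   \code{transient_days_excluded}, \code{onsets}.
#' @examples
#' p <- activity_sim_params(tau_hours = 23.62)
#' rec <- simulate_pulse_experiment(p, n_days = 16, pulse_day = 8,
#'                                  imposed_delay_min = 113)
#' phase_shift(rec, pulse_day = 8)$delay_minutes
#' @export
phase_shift <- function(record, pulse_day, pre_days = 7, post_days = 7,
                        transient_days = 2, min_fit_days = 5, ...) {
  stopifnot(inherits(record, "activity_record"))
  dm <- fold_days(record)
  onsets <- unwrap_onsets(detect_onsets(dm, ...))
  days <- seq_along(onsets)
  pre_idx <- days[days > pulse_day - pre_days & days <= pulse_day]
  post_start <- pulse_day + 1L + transient_days
  post_idx <- days[days >= post_start & days < post_start + post_days]
  pre_ok <- pre_idx[!is.na(onsets[pre_idx])]
  post_ok <- post_idx[!is.na(onsets[post_idx])]
  if (length(pre_ok) < min_fit_days)
    stop(sprintf("insufficient onsets on the pre-pulse side (%d < %d)",
                 length(pre_ok), min_fit_days))
  if (length(post_ok) < min_fit_days)
    stop(sprintf("insufficient onsets on the post-pulse side (%d < %d)",
                 length(post_ok), min_fit_days))
  pre_fit <- stats::lm(onsets[pre_ok] ~ pre_ok)
  post_fit <- stats::lm(onsets[post_ok] ~ post_ok)
  d1 <- pulse_day + 1                      # first post-pulse day
  pred <- function(fit, d) sum(stats::coef(fit) * c(1, d))
  delay <- pred(post_fit, d1) - pred(pre_fit, d1)
  structure(list(delay_minutes = delay,
                 pre_fit = stats::coef(pre_fit),
                 post_fit = stats::coef(post_fit),
                 pulse_day = pulse_day,
                 transient_days_excluded = transient_days,
                 onsets = onsets),
            class = "phase_shift")
}

#' @export
print.phase_shift <- function(x, ...) {
  kind <- if (x$delay_minutes >= 0) "delay" else "advance"
  cat(sprintf("<phase_shift> %.1f min %s (pulse day %d, %d transient days excluded)\n",
              abs(x$delay_minutes), kind, x$pulse_day,
              x$transient_days_excluded))
  cat(sprintf("  pre slope %.2f min/day, post slope %.2f min/day\n",
              x$pre_fit[2], x$post_fit[2]))
  invisible(x)
}

#' Activity in subjective night under a skeleton photoperiod
#'
#' Percentage of daily activity occurring in the declared 12-h
#' subjective-night window (between the evening and morning light pulses of
#' the 1:11:1:11 LDLD skeleton), averaged over days. Quantifies relative
#' entrainment to morning versus evening photic cues.
#'
#' @param record an \code{\link{activity_record}} under a SKELETON schedule.
#' @return percentage in [0, 100] with attribute \code{days_excluded}.
#' @export
subjective_night_activity <- function(record) {
  stopifnot(inherits(record, "activity_record"))
  if (record$schedule$regime != "SKELETON")
    stop("subjective_night_activity requires a SKELETON schedule")
  sched <- record$schedule
  .pct_in_window(record, function(h) in_dark(h, sched))
}
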