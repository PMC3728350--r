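#' Parameters for the synthetic actogram generator
#'
#' Phenomenological ground truth for a wheel-running record: a daily active
#' phase of length \code{alpha_minutes} whose onset is locked to lights-off
#' under LD (or to the subjective-night start under a skeleton) and drifts
#' by \code{(tau_hours - 24) * 60} minutes per day under DD, perturbed by
#' Gaussian onset jitter; counts at \code{mean_rate} per hour inside the
#' active phase, optionally interrupted by a random gap process, Poisson
#' count noise, and light masking. Under LD a \code{nocturnality_target}
#' reallocates counts so the dark-phase share of activity hits the target.
#'
#' @param tau_hours free-running period in hours (20-28; default 23.62).
#' @param alpha_minutes active-phase duration (default 613 min, about the
#'   10 h consolidated active phase of a young wild-type mouse).
#' @param mean_rate counts per hour inside the active phase (default 1200,
#'   a typical young-adult wheel rate).
#' @param nocturnality_target fraction of counts in the dark window under
#'   LD/skeleton (default NULL = no reallocation; active phase inside the
#'   dark already gives 100\%).
#' @param onset_jitter_sd_min SD of daily onset jitter in minutes
#'   (default 0).
#' @param gap_rate_per_hr rate of within-active-phase quiescent gaps
#'   (default 0).
#' @param mean_gap_min mean gap duration in minutes (default 10).
#' @param noise \code{"NONE"} (deterministic given seed) or
#'   \code{"POISSON"} (counts sampled around their expectation).
#' @param masking_light_suppression fraction by which light suppresses
#'   counts falling in the light (default 0).
#' @param seed RNG seed recorded in the output metadata (default 1).
#' @return an object of class \code{"activity_sim_params"}.
#' @export
activity_sim_params <- function(tau_hours = 23.62, alpha_minutes = 613,
                                mean_rate = 1200,
                                nocturnality_target = NULL,
                                onset_jitter_sd_min = 0,
                                gap_rate_per_hr = 0, mean_gap_min = 10,
                                noise = c("NONE", "POISSON"),
                                masking_light_suppression = 0,
                                seed = 1) {
  noise <- match.arg(noise)
  if (tau_hours < 20 || tau_hours > 28)
    stop("tau_hours must lie in [20, 28]")
  if (alpha_minutes <= 0 || alpha_minutes > 1440)
    stop("alpha_minutes must lie in (0, 1440]")
  if (mean_rate <= 0) stop("mean_rate must be positive")
  if (!is.null(nocturnality_target) &&
      (nocturnality_target <= 0 || nocturnality_target > 1))
    stop("nocturnality_target must lie in (0, 1]")
  if (masking_light_suppression < 0 || masking_light_suppression > 1)
    stop("masking_light_suppression must lie in [0, 1]")
  structure(list(tau_hours = tau_hours, alpha_minutes = alpha_minutes,
                 mean_rate = mean_rate,
                 nocturnality_target = nocturnality_target,
                 onset_jitter_sd_min = onset_jitter_sd_min,
                 gap_rate_per_hr = gap_rate_per_hr,
                 mean_gap_min = mean_gap_min, noise = noise,
                 masking_light_suppression = masking_light_suppression,
                 seed = seed),
            class = "activity_sim_params")
}

# counts vector from active intervals [start_min, end_min) in record minutes
.counts_from_intervals <- function(intervals, n_bins, bin_min, rate_per_min) {
  e <- numeric(n_bins)
  for (r in seq_len(nrow(intervals))) {
    s <- intervals[r, 1]; t <- intervals[r, 2]
    if (t <= 0) next
    b0 <- max(0L, floor(s / bin_min))
    b1 <- min(n_bins - 1L, ceiling(t / bin_min) - 1L)
    if (b1 < b0) next
    for (b in b0:b1) {
      lo <- b * bin_min; hi <- lo + bin_min
      ov <- max(0, min(hi, t) - max(lo, s))
      e[b + 1L] <- e[b + 1L] + ov * rate_per_min
    }
  }
  e
}

# distribute `total` integer counts over `n` bins by largest remainder
.spread_integer <- function(total, n) {
  if (n == 0 || total <= 0) return(integer(n))
  base <- total %/% n
  out <- rep.int(base, n)
  extra <- total - base * n
  if (extra > 0) out[seq_len(extra)] <- out[seq_len(extra)] + 1L
  out
}

#' Simulate a binned activity record
#'
#' See \code{\link{activity_sim_params}} for the generative model. With
#' \code{noise = "NONE"} and zero jitter the output is a deterministic
#' function of the parameters; any randomness is drawn from a single stream
#' seeded by \code{params$seed}, recorded in the \code{sim_params}
#' attribute.
#'
#' @param params an \code{\link{activity_sim_params}}.
#' @param schedule a \code{\link{light_schedule}} (default DD).
#' @param n_days number of days to generate (default 10).
#' @param bin_minutes bin width in minutes (default 3).
#' @return an \code{\link{activity_record}} with attribute \code{sim_params}
#'   (the generating parameters) and \code{onsets_true} (the generating
#'   onset minute of each day).
#' @examples
#' rec <- simulate_activity(activity_sim_params(tau_hours = 23.62),
#'                          schedule = light_schedule("DD"))
#' @export
simulate_activity <- function(params, schedule = light_schedule("DD"),
                              n_days = 10, bin_minutes = 3) {
  stopifnot(inherits(params, "activity_sim_params"),
            inherits(schedule, "light_schedule"))
  if (!is.null(params$nocturnality_target) && schedule$regime == "DD")
    stop("nocturnality_target requires an LD or SKELETON schedule")
  set.seed(params$seed)
  bpd <- as.integer(round(1440 / bin_minutes))
  n_bins <- n_days * bpd
  rate_per_min <- params$mean_rate / 60

  dk <- dark_window(schedule)
  night_start <- dk[1, 1] * 60            # onset anchor under entrainment
  drift <- (params$tau_hours - 24) * 60
  d <- seq_len(n_days) - 1
  onset <- if (schedule$regime == "DD") night_start + drift * d
           else rep(night_start, n_days)
  if (params$onset_jitter_sd_min > 0)
    onset <- onset + stats::rnorm(n_days, 0, params$onset_jitter_sd_min)
  starts <- 1440 * d + onset
  iv <- cbind(starts, starts + params$alpha_minutes)

  # quiescent gaps inside the active phase
  if (params$gap_rate_per_hr > 0) {
    gaps <- list()
    for (r in seq_len(nrow(iv))) {
      len_h <- params$alpha_minutes / 60
      ng <- stats::rpois(1, params$gap_rate_per_hr * len_h)
      if (ng > 0) {
        gs <- iv[r, 1] + stats::runif(ng, 0, params$alpha_minutes)
        gd <- stats::rexp(ng, 1 / params$mean_gap_min)
        gaps[[length(gaps) + 1L]] <- cbind(gs, pmin(gs + gd, iv[r, 2]))
      }
    }
  } else gaps <- list()

  e <- .counts_from_intervals(iv, n_bins, bin_minutes, rate_per_min)
  if (length(gaps)) {
    g <- do.call(rbind, gaps)
    e <- e - .counts_from_intervals(g, n_bins, bin_minutes, rate_per_min)
    e[e < 0] <- 0
  }

  mid_h <- ((seq_len(n_bins) - 0.5) * bin_minutes / 60) %% 24
  dark <- if (schedule$regime == "DD") rep(TRUE, n_bins)
          else in_dark(mid_h, schedule)
  if (params$masking_light_suppression > 0 && schedule$regime != "DD")
    e[!dark] <- e[!dark] * (1 - params$masking_light_suppression)

  counts <- if (params$noise == "POISSON") stats::rpois(n_bins, e)
            else as.integer(round(e))

  # reallocate counts so the expected dark share matches the target
  t <- params$nocturnality_target
  if (!is.null(t) && schedule$regime != "DD") {
    day_of_bin <- (seq_len(n_bins) - 1L) %/% bpd
    for (dd in unique(day_of_bin)) {
      sel <- day_of_bin == dd
      D <- sum(counts[sel & dark])
      light_idx <- which(sel & !dark)
      L <- round(D * (1 - t) / t)
      if (params$noise == "POISSON" && L > 0) {
        counts[light_idx] <- stats::rpois(length(light_idx),
                                          L / length(light_idx))
      } else {
        counts[light_idx] <- .spread_integer(L, length(light_idx))
      }
    }
  }

  rec <- activity_record(counts, bin_minutes = bin_minutes,
                         start_time = 0, schedule = schedule)
  attr(rec, "sim_params") <- params
  attr(rec, "onsets_true") <- onset
  rec
}

#' Simulate a light-pulse phase-shift experiment
#'
#' A DD record whose activity onsets follow the free-running line, then
#' shift abruptly by \code{imposed_delay_min} (positive = delay) from the
#' day after \code{pulse_day}, optionally approaching the full shift
#' linearly over \code{transient_days} transient cycles. To keep the
#' construction exactly recoverable at bin resolution, the daily drift and
#' the imposed shift are snapped to the bin grid (the effective tau is the
#' nearest bin-commensurate period; see the sim_params attribute).
#'
#' @param params an \code{\link{activity_sim_params}} (tau, alpha, rate,
#'   jitter and noise are honoured; nocturnality_target is ignored in DD).
#' @param n_days total days (default 16).
#' @param pulse_day 1-based day of the pulse; the shift appears from
#'   \code{pulse_day + 1} (must lie inside the record).
#' @param imposed_delay_min imposed shift in minutes, positive for a delay.
#' @param transient_days days over which the shift develops linearly
#'   (default 0 = abrupt).
#' @param bin_minutes bin width (default 1, so minute-valued shifts are
#'   exactly representable).
#' @return an \code{\link{activity_record}} (DD) with attributes
#'   \code{sim_params}, \code{onsets_true}, \code{pulse_day},
#'   \code{imposed_delay_min}.
#' @export
simulate_pulse_experiment <- function(params, n_days = 16, pulse_day = 8,
                                      imposed_delay_min, transient_days = 0,
                                      bin_minutes = 1) {
  stopifnot(inherits(params, "activity_sim_params"))
  if (pulse_day < 1 || pulse_day >= n_days)
    stop("pulse_day must lie inside the record")
  set.seed(params$seed)
  bpd <- as.integer(round(1440 / bin_minutes))
  n_bins <- n_days * bpd
  rate_per_min <- params$mean_rate / 60

  drift <- round((params$tau_hours - 24) * 60 / bin_minutes) * bin_minutes
  shift_full <- round(imposed_delay_min / bin_minutes) * bin_minutes
  d <- seq_len(n_days)
  k <- d - pulse_day                        # post-pulse cycle number
  ramp <- ifelse(k <= 0, 0, pmin(1, k / (transient_days + 1)))
  onset <- 720 + drift * (d - 1) + shift_full * ramp
  if (params$onset_jitter_sd_min > 0)
    onset <- onset + stats::rnorm(n_days, 0, params$onset_jitter_sd_min)
  starts <- 1440 * (d - 1) + onset
  iv <- cbind(starts, starts + params$alpha_minutes)
  e <- .counts_from_intervals(iv, n_bins, bin_minutes, rate_per_min)
  counts <- if (params$noise == "POISSON") stats::rpois(n_bins, e)
            else as.integer(round(e))
  rec <- activity_record(counts, bin_minutes = bin_minutes,
                         start_time = 0, schedule = light_schedule("DD"))
  attr(rec, "sim_params") <- params
  attr(rec, "onsets_true") <- onset
  attr(rec, "pulse_day") <- pulse_day
  attr(rec, "imposed_delay_min") <- shift_full
  rec
}

#' Parameters for the synthetic mobility-trace generator
#'
#' Two-state (sleep/wake) bout structure with day/night-specific sleep
#' fractions and mean bout durations; per-second immobility is
#' \code{immobility_in_sleep} while asleep and \code{immobility_in_wake}
#' while awake, plus clipped Gaussian jitter.
#'
#' @param day_sleep_fraction,night_sleep_fraction target fraction of each
#'   12-h window spent asleep (defaults 0.75 day / 0.35 night, a typical
#'   nocturnal-mouse pattern).
#' @param mean_bout_min_day,mean_bout_min_night mean sleep-bout durations
#'   in minutes (defaults 14 and 8).
#' @param immobility_in_sleep immobile-area fraction while asleep
#'   (default 0.98).
#' @param immobility_in_wake immobile-area fraction while awake
#'   (default 0.2).
#' @param jitter_sd SD of per-second immobility jitter (default 0).
#' @param seed RNG seed (default 1).
#' @return an object of class \code{"sleep_sim_params"}.
#' @export
sleep_sim_params <- function(day_sleep_fraction = 0.75,
                             night_sleep_fraction = 0.35,
                             mean_bout_min_day = 14,
                             mean_bout_min_night = 8,
                             immobility_in_sleep = 0.98,
                             immobility_in_wake = 0.2,
                             jitter_sd = 0, seed = 1) {
  for (f in c(day_sleep_fraction, night_sleep_fraction))
    if (f < 0 || f > 1) stop("sleep fractions must lie in [0, 1]")
  for (m in c(mean_bout_min_day, mean_bout_min_night))
    if (m <= 0) stop("mean bout durations must be positive")
  for (f in c(immobility_in_sleep, immobility_in_wake))
    if (f < 0 || f > 1) stop("immobility fractions must lie in [0, 1]")
  feasible <- function(f, m) f == 0 || f == 1 || m * 60 > 40
  if (!feasible(day_sleep_fraction, mean_bout_min_day) ||
      !feasible(night_sleep_fraction, mean_bout_min_night))
    stop("infeasible: mean sleep bout must exceed the 40-s scoring minimum")
  structure(list(day_sleep_fraction = day_sleep_fraction,
                 night_sleep_fraction = night_sleep_fraction,
                 mean_bout_min_day = mean_bout_min_day,
                 mean_bout_min_night = mean_bout_min_night,
                 immobility_in_sleep = immobility_in_sleep,
                 immobility_in_wake = immobility_in_wake,
                 jitter_sd = jitter_sd, seed = seed),
            class = "sleep_sim_params")
}

#' Simulate a per-second mobility trace
#'
#' Each 12-h window (day ZT 0-12, night ZT 12-24) is filled with
#' alternating wake and sleep bouts. Sleep bouts are 40 s plus an
#' exponential excess so every generated episode clears the scoring
#' minimum; wake bouts are exponential with mean chosen so the long-run
#' sleep fraction matches the window's target. The ground-truth bout table
#' is attached as the \code{truth} attribute.
#'
#' @param params a \code{\link{sleep_sim_params}}.
#' @param schedule a \code{\link{light_schedule}} (default LD).
#' @param n_days days to generate (default 3).
#' @return a \code{\link{mobility_trace}} (1-s samples, start ZT0) with
#'   attributes \code{sim_params} and \code{truth} (data frame of
#'   ground-truth sleep episodes: \code{start_sec}, \code{end_sec}).
#' @export
simulate_mobility <- function(params, schedule = light_schedule("LD"),
                              n_days = 3) {
  stopifnot(inherits(params, "sleep_sim_params"))
  set.seed(params$seed)
  total_sec <- n_days * 86400
  asleep <- logical(total_sec)
  truth <- list()
  for (w in seq_len(n_days * 2)) {
    w0 <- (w - 1) * 43200                  # window start in seconds
    is_day <- (w %% 2) == 1                # ZT 0-12 windows are odd
    f <- if (is_day) params$day_sleep_fraction else params$night_sleep_fraction
    mb <- 60 * (if (is_day) params$mean_bout_min_day else
                params$mean_bout_min_night)
    if (f == 0) next
    if (f == 1) {
      asleep[(w0 + 1):(w0 + 43200)] <- TRUE
      truth[[length(truth) + 1L]] <- c(w0, w0 + 43200)
      next
    }
    mean_wake <- mb * (1 - f) / f
    pos <- 0
    state_sleep <- FALSE                   # windows open with wake
    while (pos < 43200) {
      if (state_sleep) {
        dur <- 40 + stats::rexp(1, 1 / max(mb - 40, 1))
        dur <- min(round(dur), 43200 - pos)
        # a window-truncated episode below the scoring minimum stays wake
        if (dur >= 40) {
          asleep[(w0 + pos + 1):(w0 + pos + dur)] <- TRUE
          truth[[length(truth) + 1L]] <- c(w0 + pos, w0 + pos + dur)
        }
      } else {
        dur <- max(1, round(stats::rexp(1, 1 / mean_wake)))
        dur <- min(dur, 43200 - pos)
      }
      pos <- pos + dur
      state_sleep <- !state_sleep
    }
  }
  imm <- ifelse(asleep, params$immobility_in_sleep, params$immobility_in_wake)
  if (params$jitter_sd > 0)
    imm <- pmin(1, pmax(0, imm + stats::rnorm(total_sec, 0, params$jitter_sd)))
  tr <- mobility_trace(imm, sample_seconds = 1, start_time = 0,
                       schedule = schedule)
  tt <- if (length(truth)) {
    m <- do.call(rbind, truth)
    data.frame(start_sec = m[, 1], end_sec = m[, 2])
  } else data.frame(start_sec = numeric(), end_sec = numeric())
  attr(tr, "sim_params") <- params
  attr(tr, "truth") <- tt
  tr
}
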