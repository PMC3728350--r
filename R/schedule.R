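#' Lighting schedule
#'
#' Describes the photic regime an animal was housed under, on a fixed 24-h
#' frame anchored at ZT0 (Zeitgeber Time 0 = lights-on under LD). Three
#' regimes are supported:
#' \describe{
#'   \item{\code{"LD"}}{a 12:12 light:dark cycle, lights on over one 12-h
#'     interval (default ZT 0--12);}
#'   \item{\code{"DD"}}{constant darkness; ZT labels are retained from the
#'     last LD cycle as "projected" ZT, and a declared 12-h subjective-night
#'     window stands in for the dark phase;}
#'   \item{\code{"SKELETON"}}{a 1:11:1:11 LDLD skeleton photoperiod: two 1-h
#'     light pulses 11 h apart framing the subjective day, with a declared
#'     12-h subjective-night window between the evening and morning pulse.}
#' }
#'
#' @param regime one of \code{"LD"}, \code{"DD"}, \code{"SKELETON"}.
#' @param lights_on list of \code{c(start_hour, end_hour)} light intervals
#'   within \code{[0, 24)}. Defaults: \code{list(c(0, 12))} for LD,
#'   \code{list(c(0, 1), c(12, 13))} for SKELETON, \code{list()} for DD.
#' @param subjective_night \code{c(start_hour, end_hour)} declared 12-h
#'   subjective-night window, required for DD and SKELETON (default
#'   \code{c(12, 24)}). Ignored for LD, where the dark window is the
#'   complement of the light interval.
#'
#' @return an object of class \code{"light_schedule"}.
#' @examples
#' light_schedule("LD")
#' light_schedule("SKELETON")
#' @export
light_schedule <- function(regime = c("LD", "DD", "SKELETON"),
                           lights_on = NULL,
                           subjective_night = c(12, 24)) {
  regime <- match.arg(regime)
  if (is.null(lights_on)) {
    lights_on <- switch(regime,
      LD       = list(c(0, 12)),
      DD       = list(),
      SKELETON = list(c(0, 1), c(12, 13)))
  }
  if (length(lights_on) > 0 && !is.list(lights_on)) lights_on <- list(lights_on)
  for (iv in lights_on) {
    if (length(iv) != 2 || iv[1] < 0 || iv[2] > 24 || iv[1] >= iv[2])
      stop("each lights_on interval must be (start, end) within [0, 24)")
  }
  if (length(lights_on) > 1) {
    o <- order(vapply(lights_on, `[`, 0, 1))
    lights_on <- lights_on[o]
    for (i in seq_len(length(lights_on) - 1L))
      if (lights_on[[i]][2] > lights_on[[i + 1L]][1])
        stop("lights_on intervals overlap")
  }
  if (regime == "LD") {
    if (length(lights_on) != 1L ||
        abs(diff(lights_on[[1]]) - 12) > 1e-9)
      stop("LD requires exactly one 12-h light interval")
  } else if (regime == "DD") {
    if (length(lights_on) != 0L) stop("DD has no light intervals")
  } else {
    if (length(lights_on) != 2L ||
        any(abs(vapply(lights_on, diff, 0) - 1) > 1e-9))
      stop("SKELETON requires exactly two 1-h light pulses")
    gap <- lights_on[[2]][1] - lights_on[[1]][2]
    if (abs(gap - 11) > 1e-9 && abs((24 - diff(range(unlist(lights_on)))) - 11) > 1e-9)
      stop("SKELETON pulses must be separated by 11-h dark gaps (1:11:1:11)")
  }
  if (regime != "LD") {
    if (length(subjective_night) != 2 ||
        abs(diff(subjective_night) - 12) > 1e-9)
      stop("subjective_night must be a 12-h (start, end) window")
  }
  structure(list(regime = regime, lights_on = lights_on,
                 subjective_night = if (regime == "LD") NULL else subjective_night,
                 cycle_hours = 24),
            class = "light_schedule")
}

#' @export
print.light_schedule <- function(x, ...) {
  cat("<light_schedule> regime:", x$regime, "\n")
  if (length(x$lights_on))
    cat("  lights on:",
        paste(vapply(x$lights_on,
                     function(iv) sprintf("ZT %g-%g", iv[1], iv[2]), ""),
              collapse = ", "), "\n")
  dk <- dark_window(x)
  cat("  dark/subjective night: ZT",
      paste(sprintf("%g-%g", dk[, 1], dk[, 2]), collapse = ", ZT "), "\n")
  invisible(x)
}

#' Dark (or subjective-night) window of a schedule
#'
#' For LD the complement of the light interval within the 24-h frame; for DD
#' and SKELETON the declared subjective-night window. Intervals crossing
#' midnight are split.
#'
#' @param schedule a \code{\link{light_schedule}}.
#' @return a two-column matrix of (start_hour, end_hour) rows within [0, 24].
#' @export
dark_window <- function(schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (schedule$regime == "LD") {
    iv <- schedule$lights_on[[1]]
    segs <- list()
    if (iv[1] > 0) segs <- c(segs, list(c(0, iv[1])))
    if (iv[2] < 24) segs <- c(segs, list(c(iv[2], 24)))
    return(do.call(rbind, segs))
  }
  s <- schedule$subjective_night[1] %% 24
  e <- s + 12
  if (e <= 24) matrix(c(s, e), 1) else rbind(c(s, 24), c(0, e - 24))
}

# TRUE for each hour-of-day value falling in the dark window
in_dark <- function(hours, schedule) {
  dk <- dark_window(schedule)
  h <- hours %% 24
  out <- rep(FALSE, length(h))
  for (r in seq_len(nrow(dk))) out <- out | (h >= dk[r, 1] & h < dk[r, 2])
  out
}
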