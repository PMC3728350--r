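#' Chi-square periodogram (Sokolove-Bushell)
#'
#' Scans candidate periods and, for each, folds the series at that period and
#' measures how much of the total variance is explained by the folded
#' (column-mean) profile. For a candidate of \code{p} bins, using the first
#' \code{N' = K * p} points (\code{K} complete cycles),
#' \deqn{Q_p = K N' \sum_h (M_h - \bar M)^2 / \sum_i (x_i - \bar M)^2}
#' where \eqn{M_h} are the \code{p} column means and \eqn{\bar M} the grand
#' mean of the \code{N'} points. Under white noise \eqn{Q_p} is approximately
#' chi-square with \code{p - 1} degrees of freedom, giving the rising
#' significance line \code{qchisq(1 - alpha, p - 1)} seen on standard
#' periodogram plots. \eqn{Q_p \le N'} with equality for a perfectly periodic
#' signal, so the normalized power \eqn{\%V = Q_p \times 100 / n} (with
#' \code{n} the number of points examined at the peak) lies in [0, 100].
#'
#' The free-running period tau is the candidate with maximal \eqn{Q_p} among
#' those exceeding the significance line (smallest period wins ties); if no
#' candidate is significant the record is reported arrhythmic and tau is
#' \code{NA}. Candidate periods are integer multiples of the bin width.
#' Gap bins (\code{NA}) are excluded from the means and from \code{n}.
#'
#' @param record an \code{\link{activity_record}} spanning at least two
#'   cycles of \code{max_period_h}.
#' @param min_period_h,max_period_h scan range in hours (default 20-28).
#' @param alpha significance level for the chi-square line (default 0.05).
#' @return an object of class \code{"chisq_periodogram"}: a list with
#'   \code{period_h}, \code{Qp}, \code{sig_line}, \code{tau_hours},
#'   \code{power_pct}, \code{n_points}, \code{alpha}.
#' @examples
#' rec <- simulate_activity(activity_sim_params(tau_hours = 24), n_days = 6,
#'                          schedule = light_schedule("DD"))
#' pg <- chisq_periodogram(rec)
#' pg$tau_hours
#' @export
chisq_periodogram <- function(record, min_period_h = 20, max_period_h = 28,
                              alpha = 0.05) {
  stopifnot(inherits(record, "activity_record"))
  x <- as.numeric(record$counts)
  bin_h <- record$bin_minutes / 60
  if (length(x) * bin_h < 2 * max_period_h)
    stop("record must span at least two cycles of max_period_h")
  p_bins <- seq.int(ceiling(min_period_h / bin_h - 1e-9),
                    floor(max_period_h / bin_h + 1e-9))
  p_bins <- p_bins[p_bins >= 2]
  Qp <- numeric(length(p_bins))
  Np <- integer(length(p_bins))
  for (j in seq_along(p_bins)) {
    p <- p_bins[j]
    K <- length(x) %/% p
    xx <- x[seq_len(K * p)]
    Mh <- rowMeans(matrix(xx, nrow = p), na.rm = TRUE)  # phase-fold profile
    n_used <- sum(!is.na(xx))
    Mbar <- mean(xx, na.rm = TRUE)
    denom <- sum((xx - Mbar)^2, na.rm = TRUE)
    Qp[j] <- if (denom <= 0) 0 else
      K * n_used * sum((Mh - Mbar)^2) / denom
    Np[j] <- n_used
  }
  sig <- stats::qchisq(1 - alpha, df = p_bins - 1)
  signif_idx <- which(Qp > sig)
  if (length(signif_idx)) {
    peak <- signif_idx[which.max(Qp[signif_idx])]
    # ties broken toward the smallest period
    best <- Qp[peak]
    peak <- signif_idx[which(Qp[signif_idx] >= best - 1e-12)][1]
    tau <- p_bins[peak] * bin_h
    power <- Qp[peak] * 100 / Np[peak]
    n_at_peak <- Np[peak]
  } else {
    tau <- NA_real_
    power <- NA_real_
    n_at_peak <- NA_integer_
  }
  structure(list(period_h = p_bins * bin_h, Qp = Qp, sig_line = sig,
                 tau_hours = tau, power_pct = power, n_points = n_at_peak,
                 alpha = alpha, bin_minutes = record$bin_minutes),
            class = "chisq_periodogram")
}

#' Rhythm power as a percentage of variance
#'
#' Normalizes the periodogram peak amplitude by the number of data points
#' examined: \code{Qp_peak * 100 / n}.
#'
#' @param Qp_peak peak chi-square periodogram statistic (>= 0).
#' @param n number of data points examined (> 0).
#' @return power in percent.
#' @examples
#' power_pct(2400, 4800)  # 50
#' @export
power_pct <- function(Qp_peak, n) {
  if (n <= 0) stop("n must be positive")
  if (Qp_peak < 0) stop("Qp_peak must be non-negative")
  Qp_peak * 100 / n
}

#' @export
print.chisq_periodogram <- function(x, ...) {
  cat("<chisq_periodogram>", length(x$period_h), "candidate periods,",
      sprintf("%.2f-%.2f h\n", min(x$period_h), max(x$period_h)))
  if (is.na(x$tau_hours)) {
    cat(sprintf("  arrhythmic: no candidate exceeds the %g%% significance line\n",
                100 * (1 - x$alpha)))
  } else {
    cat(sprintf("  tau = %.2f h, power = %.1f %%V (n = %d)\n",
                x$tau_hours, x$power_pct, x$n_points))
  }
  invisible(x)
}

#' @export
summary.chisq_periodogram <- function(object, ...) {
  df <- data.frame(period_h = object$period_h, Qp = object$Qp,
                   sig_line = object$sig_line)
  attr(df, "tau_hours") <- object$tau_hours
  attr(df, "power_pct") <- object$power_pct
  df
}

#' Plot a chi-square periodogram
#'
#' Qp against candidate period with the rising chi-square significance line
#' drawn as the intersecting diagonal; the peak, when significant, is marked.
#'
#' @param x a \code{"chisq_periodogram"}.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
plot.chisq_periodogram <- function(x, ...) {
  graphics::plot(x$period_h, x$Qp, type = "l",
                 xlab = "Period (h)", ylab = expression(Q[p]), ...)
  graphics::lines(x$period_h, x$sig_line, lty = 2)
  if (!is.na(x$tau_hours)) {
    i <- which.min(abs(x$period_h - x$tau_hours))
    graphics::points(x$tau_hours, x$Qp[i], pch = 19)
    graphics::mtext(sprintf("tau = %.2f h, %.1f %%V", x$tau_hours, x$power_pct),
                    side = 3, line = 0.2, adj = 1, cex = 0.8)
  }
  invisible(x)
}
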