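# Independent brute-force oracles. These deliberately re-derive each result
# from the definitions by direct scanning/enumeration, sharing no code with
# the package implementation.

# Activity-bout oracle: active bins grouped wherever the run of inactive
# bins between them is shorter than the gap tolerance; groups shorter than
# the minimum span are dropped. Returns (start_bin, end_bin) 1-based
# inclusive.
oracle_bouts <- function(counts, bin_min, thr = 0,
                         max_gap_min = 21, min_bout_min = 21) {
  active <- which(!is.na(counts) & counts > thr)
  if (!length(active))
    return(data.frame(start = integer(), end = integer()))
  gap_bins <- max_gap_min / bin_min
  brk <- which(diff(active) - 1 >= gap_bins)
  grp_start <- active[c(1, brk + 1)]
  grp_end <- active[c(brk, length(active))]
  span <- grp_end - grp_start + 1
  keep <- span * bin_min >= min_bout_min
  data.frame(start = grp_start[keep], end = grp_end[keep])
}

# Sleep-flag oracle: literal per-sample scan marking maximal runs of
# immobility >= threshold lasting >= min_seconds samples (1-s sampling).
oracle_sleep_flags <- function(imm, threshold = 0.95, min_seconds = 40) {
  n <- length(imm)
  flags <- logical(n)
  i <- 1
  while (i <= n) {
    if (imm[i] >= threshold) {
      j <- i
      while (j < n && imm[j + 1] >= threshold) j <- j + 1
      if (j - i + 1 >= min_seconds) flags[i:j] <- TRUE
      i <- j + 1
    } else i <- i + 1
  }
  flags
}

# Direct evaluation of the chi-square periodogram statistic at one
# candidate period (in bins), from the definition.
oracle_Qp <- function(x, p) {
  K <- length(x) %/% p
  xx <- x[1:(K * p)]
  Mh <- numeric(p)
  for (h in 1:p) Mh[h] <- mean(xx[seq(h, K * p, by = p)])
  Mbar <- mean(xx)
  denom <- sum((xx - Mbar)^2)
  if (denom <= 0) return(0)
  K * (K * p) * sum((Mh - Mbar)^2) / denom
}

# a square-wave activity record: active [on_min, on_min + alpha) each day
square_record <- function(n_days = 10, bin_min = 3, on_min = 720,
                          alpha_min = 720, level = 60L,
                          schedule = light_schedule("LD")) {
  bpd <- 1440 / bin_min
  day <- integer(bpd)
  mids <- (seq_len(bpd) - 0.5) * bin_min
  day[((mids - on_min) %% 1440) < alpha_min] <- level  # wraps midnight
  activity_record(rep(day, n_days), bin_minutes = bin_min,
                  schedule = schedule)
}
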