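---
title: "Methods: circadian activity and immobility-defined sleep analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian activity and immobility-defined sleep analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circabehave)
```

This vignette documents the models, conventions and numerical choices
behind each analysis stage, and what the synthetic-data generator does and
does not emulate.

## Data model and time conventions

Activity arrives as event counts in fixed-width bins (default 3 min, the
usual wheel-running acquisition setting); mobility arrives as a per-second
fraction of the animal's area detected immobile. Both carry a
`light_schedule` anchoring Zeitgeber time: ZT0 is lights-on under a 12:12
LD cycle, ZT12 lights-off. Under constant darkness (DD) the ZT frame of the
last LD cycle is retained as "projected ZT", which is how actograms of
free-running animals are conventionally plotted and is what the day-folding
utilities assume; the free run itself is recovered analytically (the
periodogram and the onset regressions), so the choice of anchor only fixes
the plotting frame, not any estimate. Days are half-open `[ZT0, ZT0+24h)`;
`fold_days()` trims partial leading/trailing days and stacks complete days.

Recording gaps are carried as `NA` and excluded from every mean, total and
denominator. They are never zero-filled: zero-filling would deflate rates
and bias nocturnality toward whichever window holds fewer gaps.

For the skeleton photoperiod (1:11:1:11 LDLD) the two 1-h pulses are placed
at ZT 0–1 and ZT 12–13, and the declared 12-h subjective night defaults to
ZT 12–24 — the projection of the prior dark phase, so the evening pulse
hour falls at the start of subjective night. The window is an explicit
schedule field, so any other convention can be declared.

## Chi-square periodogram

For a candidate period of $p$ bins the first $N' = Kp$ points ($K$ complete
cycles; the incomplete final cycle is dropped so the null stays exact) are
folded into $p$ phase columns with means $M_h$, and

$$Q_p = \frac{K\,N' \sum_h (M_h - \bar M)^2}{\sum_i (x_i - \bar M)^2}.$$

$Q_p$ is a ratio statistic — invariant to rescaling the counts — bounded by
$N'$, with $Q_p \approx \chi^2_{p-1}$ under white noise. The significance
line is $\chi^2_{0.95}(p-1)$; tau is the candidate with maximal $Q_p$ above
the line, ties broken toward the smaller period for determinism, and a
record with no significant candidate is reported arrhythmic (`NA` tau)
rather than erroring. Candidates are integer bin multiples over 20–28 h by
default, matching the circadian scan window used on wheel data.

Rhythm power is reported as $\%V = Q_p \cdot 100/n$. The normalization $n$
is taken as the number of points actually examined at the peak candidate
($N'$, minus gap bins); with whole-record normalization the ceiling of %V
would depend on the scan range, which we judged the less defensible
reading. The chi-square null is known to be slightly conservative at small
cycle counts; at 10 recorded days the per-candidate type-I exceedance on
white noise sits near 4 % (the test suite verifies it stays within two
standard errors of 5 % over 200 simulated records).

## Scalar circadian metrics

**Average waveform** — per-bin mean and SEM across days (within animal).

**Nocturnality** — per-day percentage of counts in the dark (or
subjective-night) window, averaged across days; zero-activity days are
excluded and flagged rather than contributing an undefined ratio.

**Activity amount** — total counts divided by recorded hours.

**Alpha** — the waveform mean is the threshold, and alpha is the longest
*circularly* contiguous run of bins strictly above it, i.e. the
onset-to-offset span of the consolidated active phase. This matches the
chronobiological meaning of alpha as active-phase length; a total-time
variant (`total = TRUE`) is available for comparison with software that
sums all suprathreshold time. Alpha is invariant under adding a constant to
the waveform (the mean shifts equally) and under positive scaling.

**Onset detection** — commercial actogram software does not publish its
onset rule, so the picker here is explicit and fully parameterized: a bin
qualifies as onset if the preceding `quiet_hours` (default 4 h, at most one
violating bin) sit below threshold and at least `active_frac` (default 0.5)
of the following `active_window_h` (default 1 h) sits above, with threshold
`threshold_frac` (default 0.2) of the day's mean positive-bin count. The
defaults were chosen for robustness across the generator's jitter range and
are exposed so users can match other tools.

**Precision** — onsets are unwrapped across the 24-h boundary, regressed on
day index, and precision is the mean absolute residual in minutes. Some
published tables print onset-variability values with a negative sign (a
software convention); we report the magnitude.

**Fragmentation** — bouts/day, where a bout opens at a bin above the count
threshold (default 0), tolerates sub-threshold gaps shorter than 21 min,
and must span at least 21 min — the standard "maxgap 21 min" setting for
wheel data.

## Photic phase shifts

The light-pulse protocol is analysed Aschoff type-II style: a regression
through the onsets of the 7 days up to and including the pulse day, a
second through 7 onsets starting after 2 transient cycles, both
extrapolated to the first post-pulse day; the shift is the difference
(positive = delay). The 7/7/2 defaults follow common practice for
pulse-at-CT16 assays and are all arguments. At least 5 detected onsets are
required on each side, and the error names the deficient side.

## Immobility-defined sleep

Scoring applies two distinct rules in sequence, deliberately kept separate:

1. **Episode rule (per second):** sleep is a maximal run of samples with
   immobility ≥ threshold (default 0.95) lasting ≥ 40 s. Runs below 40 s
   are wake in full — 39 s of stillness contributes nothing.
2. **Bout rule (per minute):** after aggregating the flag to ZT-aligned
   minutes, a sleep bout is a maximal run of minutes each holding ≥ 40 s of
   sleep.

Day totals sum sleep over ZT 0–12, night totals over ZT 12–24, per complete
day, then average across days; partial days are excluded and flagged. A
bout spanning ZT 12 (or midnight) is split at the boundary so that
day/night attribution is exclusive and `day + night = total` holds exactly.
Bout-duration distributions normalize 30-min duration classes by the total
number of daytime bouts, with a finer sub-30-min variant. The threshold
sensitivity analysis rescores everything at 90/95/97 % immobility and
reports each metric's percentage change against the 95 % reference;
because the exceedance sets are nested, total sleep is non-increasing in
the threshold, which the tests assert.

## Group statistics

Metrics that pass Shapiro–Wilk normality in every group and Levene's
equal-variance test (both at α = 0.05, configurable) are compared by
one-way ANOVA (F, with $k-1$ and $N-k$ df); otherwise by Kruskal–Wallis
ANOVA on ranks (tie-corrected H against $\chi^2_{k-1}$). A significant
omnibus test unlocks Bonferroni-corrected pairwise t tests on the pooled
within-group variance (raw p × number of comparisons, capped at 1);
`bonferroni_pairwise_t()` refuses to run without a significant omnibus
p value unless forced, encoding the post hoc discipline. Repeated-measures
designs are out of scope and better served by dedicated software; the
package's outputs are plain data frames ready for export.

## Synthetic-data generator

The generator is mechanistic-phenomenological, not an oscillator model: the
analysis metrics are themselves phenomenological, so ground truth is
expressed in the same vocabulary. An activity record is a daily active
phase of length alpha whose onset is locked to lights-off under LD and
drifts by $(\tau - 24)\cdot 60$ min/day under DD, perturbed by Gaussian
jitter; counts accrue at a constant rate inside the active phase
(proportional overlap for partial bins), optionally thinned by a
Poisson-process gap model, Poisson-sampled counts, and light masking. Under
LD, a nocturnality target reallocates counts: light-phase bins receive the
integer total `round(D(1-t)/t)` spread by largest remainder, so the
realized dark share matches the target to well under 0.1 percentage point
while counts stay integers.

Defaults describe a healthy young adult mouse: τ = 23.62 h, alpha 613 min,
1200 counts/hr in the active phase — the wild-type values the recovery
tests target. The mobility generator fills each 12-h half-day with
alternating wake/sleep bouts; sleep bouts are 40 s plus an exponential
excess (so every generated episode clears the scoring minimum — a
window-truncated episode below 40 s is left as wake), wake bouts are
exponential with mean set so the long-run sleep fraction hits the window's
target (defaults 0.75 day / 0.35 night with 14- and 8-min mean bouts, a
typical nocturnal-mouse pattern). The ground-truth bout table is attached
to the trace.

The pulse-experiment generator snaps the daily drift and the imposed shift
to the bin grid (default 1-min bins), making the onset sequence exactly
linear on the grid; this is what lets the phase-shift regression recover an
imposed delay exactly, and the effective (bin-commensurate) tau is recorded
in the parameters attribute. Every generator draws from a single stream
seeded by its `seed` parameter, so identical parameters give byte-identical
records.

What the generator does **not** emulate: ultradian structure within the
active phase, gradual (rather than abrupt-or-linear) phase-shift
transients, age- or genotype-dependent trajectories, light-intensity
dependence of masking, and REM/NREM architecture beneath the binary
sleep/wake state. Passing recovery tests therefore demonstrate that the
estimators are correct for consolidated, approximately square-wave rhythms
with Gaussian onset noise — they do not certify behavior on severely
fragmented real records, where onset detection in particular will need its
thresholds tuned.

## Problem sizes and determinism

The validation suite uses 10-day records at 3-min bins (the standard
analysis window for each lighting condition), 16-day pulse experiments at
1-min bins, 2–3-day mobility traces at 1 Hz, 200-record Monte-Carlo
calibration of the periodogram null, and 1000-record oracle-equivalence
sweeps for the two run-length scanners. All stochastic tests fix their
seeds; estimator ties (equal $Q_p$) resolve toward the smaller period, and
all boundary conventions (half-open days, strict thresholds on counts,
non-strict ≥ on immobility and ≥ 40 s minima) are asserted by boundary
tests.
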