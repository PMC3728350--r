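# circabehave

Analysis of circadian locomotor activity and immobility-defined sleep in
rodents. The package covers the standard behavioral-chronobiology pipeline
used to phenotype mouse lines (for example neurodegeneration models aging
under a battery of lighting conditions): wheel-running records in fixed bins
are screened for rhythmicity, scalar circadian parameters are extracted per
animal, photic responses are quantified, video-derived immobility traces are
scored as sleep, and genotype groups are compared with the field's usual
statistics. A synthetic-data module generates actograms and mobility traces
with known ground truth so every stage is verifiable without animal data.

## What it computes

**Rhythm detection.** The chi-square periodogram of Sokolove and Bushell.
For a candidate period of *p* bins, using the first *N′ = K·p* points
(*K* complete cycles),

    Qp = K · N′ · Σ_h (M_h − M̄)² / Σ_i (x_i − M̄)²

where *M_h* are the *p* phase-column means and *M̄* the grand mean. Under
white noise *Qp* ≈ χ²(p − 1), giving the rising significance line drawn on
periodogram plots; the free-running period τ is the candidate with maximal
*Qp* above the line, and rhythm power is normalized as %V = *Qp* · 100/*n*.

**Circadian metrics.** Nocturnality (% of activity in the dark window),
activity amount (counts/hr), alpha (duration of the active phase, measured
as the longest circular run of average-waveform bins above the waveform
mean), onset precision (mean absolute residual of daily activity onsets
about their best-fit regression line), and fragmentation (activity bouts
per day, with a 21-min gap tolerance and 21-min minimum bout).

**Photic responses.** Phase shifts to a discrete light pulse, estimated
Aschoff type-II style: regression lines through the pre-pulse and post-pulse
onsets (transient cycles excluded) extrapolated to the first post-pulse day;
and the percentage of activity in subjective night under a 1:11:1:11 LDLD
skeleton photoperiod.

**Sleep.** Immobility-defined sleep: ≥ 95 % of the animal's area immobile
sustained for ≥ 40 s scores as sleep; per-minute sleep seconds, day
(ZT 0–12) and night (ZT 12–24) totals, minute-resolution sleep bouts
(≥ 40 s sleep per minute), bout-duration distributions, and sensitivity of
every metric to the 90/95/97 % threshold choice.

**Group statistics.** One-way ANOVA (F), ANOVA on ranks (Kruskal–Wallis H)
when normality or equal variance fails, and Bonferroni-corrected pooled-
variance pairwise t tests after a significant omnibus test.

## Worked example

```r
library(circabehave)

# a 10-day free-running (DD) record with a 23.62-h period
p   <- activity_sim_params(tau_hours = 23.62)
rec <- simulate_activity(p, light_schedule("DD"), n_days = 10)
chisq_periodogram(rec)
#> <chisq_periodogram> 161 candidate periods, 20.00-28.00 h
#>   tau = 23.60 h, power = 99.1 %V (n = 4720)

# an entrained LD record placing 97.5% of activity in the dark
p2   <- activity_sim_params(tau_hours = 24, nocturnality_target = 0.975)
rec2 <- simulate_activity(p2, light_schedule("LD"), n_days = 10)
circadian_metrics(rec2)
#>   nocturnality_pct power_pct activity_rev_per_hr alpha_minutes
#> 1         97.50278       100            523.9167           612
#>   fragmentation_bouts_per_day precision_minutes tau_hours
#> 1                           1      9.015343e-14        24
```

The periodogram peak lands on the scan step nearest the generating period
(23.60 h for a 3-min-bin scan of a 23.62-h rhythm); the metrics row recovers
the generator's settings: the dark-phase share (97.5 %), the bin-quantized
active phase (612 min of the requested 612.9), perfectly precise onsets
(residual ~1e-13 min), and the entrained 24.0-h period.

```r
# a light-pulse experiment with an imposed 113-min phase delay
rec3 <- simulate_pulse_experiment(p, n_days = 16, pulse_day = 8,
                                  imposed_delay_min = 113)
phase_shift(rec3, pulse_day = 8)
#> <phase_shift> 113.0 min delay (pulse day 8, 2 transient days excluded)
#>   pre slope -23.00 min/day, post slope -23.00 min/day
```

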