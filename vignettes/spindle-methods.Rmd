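---
title: "Spindle detection methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spindle detection methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents how `spindler` detects sleep spindles, how the
wavelet screening works, what the synthetic generator holds fixed as its
study conditions, and the design decisions (including two benchmark
expectations that the shipped implementation deliberately leaves red).

## Detection pipeline

`detect_spindles()` runs, in order:

1. **Band-energy series.** A frequency-domain continuous wavelet transform
   on a 0.5 Hz grid spanning 9–16 Hz. Each wavelet row is normalized to unit
   discrete L2 norm and is analytic (support on positive frequencies only);
   rows are aggregated by the arithmetic mean of squared moduli
   (`aggregate = "max"` is available as an option; see below). The default
   mother wavelet is a complex frequency B-spline, whose amplitude spectrum
   is a central B-spline of order *m* on *fc* ± *fb*/2 — a tunable,
   compactly supported band-pass in frequency.
2. **Smoothing.** 200 ms unit-area Hann convolution of the energy series.
3. **Dual thresholding.** Baseline mean and SD of the smoothed energy
   (restricted to NREM samples when a hypnogram is supplied); candidates are
   the maximal runs above mean + 1 SD that contain at least one sample above
   mean + 3 SD. Because thresholds are data-relative, detection is invariant
   to global amplitude rescaling.
4. **Filters.** Duration 0.4–2 s; 5–30 cycles, counted as positive local
   maxima of the zero-phase 9–16 Hz FIR-filtered trace (order 333 at
   1000 Hz, scaled proportionally at other rates); and band specificity —
   the event's 9–16 Hz power must be at least as large as its power in both
   flanking bands (6–8.5 and 16.5–20 Hz).
5. **Features.** Central frequency (argmax of the zero-padded amplitude
   spectrum of the de-meaned event, ≥ 8× padding), peak-to-peak amplitude
   of the filtered trace, and symmetry: `(t_peak − start)/(end − start)`
   where `t_peak` is the smoothed-energy maximum. A temporally symmetric
   event scores exactly 0.5; this invariant is asserted, exactly, in the
   acceptance suite.

## Wavelet screening

`normalized_spindle_power()` is the screening statistic: mean band energy
inside annotated spindle intervals divided by the mean outside (optionally
restricted to NREM by a hypnogram, the default analysis scope here — wake
and REM theta otherwise dilute the outside term with unrelated activity).
`grid_search_wavelet()` maximizes it over a family's parameter grid
(order *m* ∈ {1, 2, 3}, bandwidth *fb* ∈ {0.5, 1, 1.5, 2}, center
*fc* ∈ {0.5, 1, 1.5}, as applicable), and `rank_families()` compares
families by their tuned optima. For fixed-shape families the effective
center frequency is found numerically from the spectrum's argmax, so every
family maps scale to frequency consistently.

**A structural near-tie.** On narrowband synthetic events, the tuned
frequency B-spline and the tuned complex Morlet land within ~0.001 of each
other, and on the 10-min benchmark fixture the Morlet wins by 0.0008 — so
the acceptance expectation "fbsp ≥ cmor" is red. The cause is structural,
not a bug: with a dense 0.5 Hz analysis grid and mean aggregation, the
band-energy series integrates the event's energy across rows, so any
sufficiently narrow filter captures essentially all of it and the statistic
becomes nearly filter-shape independent; both families' grid winners are
their narrowest grid points. Separating the families would require events
with structured broadband contamination, which the generator's study
conditions (below) do not include, and we did not add such contamination
after the fact to manufacture a pass.

## The generator as study conditions

`synth_config()` defaults are the study conditions, fixed a priori: 3
spindles per NREM minute, central frequencies from a truncated normal
(11.5 ± 1.2 Hz, clipped to 9–16 Hz), durations uniform on 0.4–1.5 s,
asymmetric waxing–waning envelopes, event SNR 5 relative to the NREM
sigma-band background, slow waves (100 µV, 0.5–4 Hz) in NREM, theta in
wake/REM, 1/f background, and a 3× spindle-rate boost in the final 25 s of
NREM episodes that transition into REM. Hypnograms come from an
alternating-bout semi-Markov chain (REM entered only from NREM). Everything
is deterministic given the seed; `generate_recording()` returns full ground
truth.

**Sensitivity at the default SNR.** The acceptance benchmark asks for
sensitivity ≥ 0.90 and FDR ≤ 0.10 on a 60-min recording at default
settings. The shipped detector achieves FDR ≈ 0.01–0.03 but sensitivity
≈ 0.69 at SNR 5; sensitivity is monotone in SNR (≈ 0.48/0.86/0.90/0.95 at
SNR 3/5/8/12 on 20-min probes) and crosses 0.90 near SNR 8. We kept the
a-priori SNR 5 rather than raising the event amplitude (or lowering
thresholds, which would trade away the FDR) to make the benchmark pass, so
that expectation is red and documented. For calibration, detectors of this
family are typically reported near 70% sensitivity / 25% false discovery on
expert-scored real data.

**Default wavelet bandwidth.** The package default is fbsp with *m* = 2,
*fb* = 0.5, *fc* = 1. A broader *fb* = 1 kernel smears event energy in time:
on the study conditions adjacent candidates merge into > 2 s runs that the
duration filter then discards, costing sensitivity. The narrower bandwidth
was selected by the same grid-search methodology the screening module
implements, applied to held-out generator output — i.e. by the package's own
stated procedure, not by tuning against the benchmark.

**Mean vs max aggregation.** Aggregating the 9–16 Hz rows by their maximum
instead of their mean was evaluated as an alternative (it sharpens narrow
events) and measured slightly worse end to end; it remains available as
`aggregate = "max"` but is not the default.

## State dynamics

`rate_by_state()` divides state-labelled event counts by state dwell time
(zero dwell gives `NA`, not zero). `episode_rates_by_successor()` pools
events over all NREM episodes ending in REM (N2R) vs ending in wake (N2W),
excluding the final, successor-less episode. `pre_transition_profile()`
computes rates in the last 5–40 s of each transitioning episode, clipping
windows at the episode start and pooling covered minutes in the
denominator. `moving_window_rate()` tracks slow trends (30-min windows,
25-min overlap; windows with under a minute of NREM are flagged).

On long generator runs the measured 25-s pre-REM to N2W episode-rate ratio
converges to ≈ 2.6 — below the nominal 3× boost because the generator's
non-overlap rule (event duration plus a 100 ms gap) imposes a dead time
that saturates the boosted window — and the acceptance band of 2.4–3.6 is
met with hundreds of transitions.

## Unit coupling

`detect_spikes()` applies a zero-phase elliptic 600–4000 Hz band-pass
(order 4, 0.1 dB ripple, 40 dB stopband; rate ≥ 10 kHz required), thresholds
at 7.5 × median(|filtered|), groups crossings within 1 ms and times each
spike at the group extremum. `detect_bursts()` finds runs of ≥ 3 spikes
with inter-spike intervals < 6 ms preceded by ≥ 50 ms of silence; its
output is verified, exactly, against an exhaustive oracle on 1000 random
trains.

`spike_field_coupling()` averages, across spindles, ± 250 ms windows of the
9–16 Hz filtered LFP centered on each spindle's central peak, builds the
trial-averaged firing-rate curve (10 ms windows, 8 ms overlap) on the same
frame, and reports the peak normalized cross-correlation within ± 100 ms
(positive lag = spikes trail the field). Construction note: a spike train
drawn from an intensity proportional to the instantaneous filtered field
reaches coupling ≈ 0.99 with exact lag recovery (injected 5/10/20 ms lags
recovered within the 2 ms grid), whereas a deterministic comb at the field
peaks saturates near 0.6–0.8 for purely geometric reasons (a comb convolved
with the rate window is not sinusoidal). The Poisson null is summarized by
the median of a fixed batch of draws: the max-over-lags statistic has only
~50 effective degrees of freedom here, so single null draws scatter widely
around a median of ≈ 0.19.

`detect_up_states()` takes positive half-waves of the 0.5–4 Hz trace
(≥ 200 ms, peak ≥ mean absolute filtered amplitude);
`spindle_up_coincidence()` applies a 50%-of-spindle-duration overlap rule
against the UP union; `delta_power_during_spindles()` measures 4-s
Hann-windowed delta power centered on spindle midpoints;
`rate_modulation()` compares spike and burst rates between interval sets.

## Determinism and provenance

All generator randomness flows from explicit seeds through an RNG-scoped
wrapper, and the analysis path is purely deterministic: synthesizing,
detecting and writing events twice yields byte-identical files (asserted in
the acceptance suite). The CLI (`inst/cli/spindler`) records, for every
run, a JSON provenance file with the config hash, input checksums and
package version, and never modifies its inputs.
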