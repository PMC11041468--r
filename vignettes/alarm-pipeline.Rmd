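---
title: "Suppressing false SpO2 alarms with composable artifact detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suppressing false SpO2 alarms with composable artifact detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spo2cdss)
```

## The problem

Continuous pulse oximetry in the NICU produces frequent alarms, and most of
them are artifacts rather than clinical events: infant motion corrupts the
photoplethysmographic signal, probes detach, and the bedside monitor
annunciates instantly on any numeric threshold crossing. The package models
alarm generation as a pipeline of small, interchangeable components over a
common stream schema, so that artifact-detection strategies can be composed,
swapped and compared quantitatively on the axis that matters clinically:
how much of the false-alarm burden is removed, at what cost in sensitivity
to true desaturations.

## The stream model

Every component consumes and produces the same container: a uniformly
sampled numeric stream annotated per-sample with a signal-quality indicator
(SQI). Three modelling choices are load-bearing:

* **Values are immutable.** Artifact handling annotates quality; it never
  rewrites data. Symbolic tokens the monitor interlaces into the numerics
  (`"NaN"` for a dropped sample, `"^^"` for a flagged artifact, alarm code
  `5` for sensor-off) are preserved verbatim and only mapped to `NA` in the
  numeric *view*.
* **One SQ type per stream.** `"binary"` is the rank set `{0, 1}`; the
  registry of SQ types is open so new vocabularies (e.g. a continuous
  quality score) can be added without touching existing validators.
* **Integer-second grid.** Timestamps are seconds since session start.
  The monitors emit numerics at 0.5 Hz; acquisition resamples to 1 Hz by
  zero-order hold (sample duplication), never linear interpolation, because
  alarm codes and artifact tokens are categorical and must not be averaged.
  Duplication also makes the bookkeeping exact: a cohort of 79,200 native
  samples per data type becomes exactly 158,400 one-second samples. Linear
  interpolation for purely numeric streams exists behind
  `upsample_to_1hz(method = "linear")`, off by default.

Devices are aligned at their first packets and truncated to the common
span; the monitors provide no SQI, so acquisition attaches the default
binary SQI = 1 and refuses to overwrite any derived annotation.

## The artifact-detection operators

`ad_dil` maps each configured artifact symbol to a configured SQ value at
the samples where it occurs and passes every other sample's SQI through
unchanged — with the acquisition default of 1 this yields the usual binary
quality stream. `ad_fuse_sqi` combines N quality streams pointwise with
min, max or avg; avg is refused on binary inputs (the mean leaves the
domain) and warns when it leaves a rank domain fractional. `ad_diff`
exploits sensor redundancy: heart rate from ECG electrodes and pulse rate
from the optical sensor measure the same physiology, so their absolute
difference proxies optical signal quality — and since SpO2 derives from the
same optical sensor, a PR that has left HR indicts SpO2 too. The difference
is binned against a strictly increasing threshold set; a sample whose
inputs are already untrusted (SQI 0, or symbolic where a number is needed)
short-circuits to the default SQ value without arithmetic.

`ad_medfilt` is the transient suppressor: each output sample is the median
of the acceptable (non-zero SQI, numeric) samples in the trailing window of
`med_ww` samples. Three rules the operator's definition leaves open are
fixed as follows, all for causality — the filter must be implementable
sample-at-a-time on a live stream:

* the window is trailing and includes the current sample; warm-up uses
  however many samples exist;
* a window containing no acceptable sample holds the previous output (the
  first such output is the missing marker);
* an even number of candidates yields the mean of the two middle values.

The filter is implemented in compiled code (an O(n·w) masked running
median) because it sits in the inner loop of the tuning grid search; an
independent sort-based R oracle verifies it in the test suite.

## The alarm generator

The clinical event detector follows two established false-alarm-reduction
ideas — adjusted thresholds and annunciation delays — and couples the delay
to breach severity. The monitor's alarm limits are widened by the
oximeter's specified accuracy margin (3 pp by default): a low breach means
SpO2 at least 3 pp below the monitor's low limit. Per-sample breach
magnitudes (pp, zero for untrusted or symbolic samples) are summed over a
trailing buffer, so the integrated error grows with magnitude × duration; a
sustained 1-pp breach crosses the low decision threshold `DT_LO = ced_dt`
after `ced_dt` seconds, a 5-pp breach after about one fifth of that. High
breaches are compared against `DT_HI = 2·ced_dt`: high saturation is
clinically less dangerous, so the detector waits twice as long. An absolute
floor (default 60%, configurable within the clinically quoted 50–75% range)
bypasses the delay entirely: below it the sensor cannot calibrate and the
clinician must be called regardless.

Remaining numerical choices: comparisons against the decision thresholds
are strict (`>`); the integration buffer length is a fixed 240 s — it must
comfortably exceed `2·ced_dt + 1` seconds for every admissible delay (up to
60 s), otherwise a shallow sustained high breach could never accumulate
past `DT_HI`; keeping it constant across `ced_dt` also preserves the useful
monotonicity that a longer delay never asserts more alarm time. Whether
magnitude or a binary breach indicator is integrated is exposed as
`integrate = c("magnitude", "binary")`; magnitude is the default since it
realizes the magnitude-and-duration reading. Episodes are maximal runs of
asserted samples; there is no buffer reset at onset, an episode persists
while any condition holds, and one clear sample separates episodes.

## The four preset compositions

Preset #1 de-interlaces the SpO2 and alarm-status streams and min-fuses
their quality onto SpO2 before the detector. #2 inserts the median filter
between fusion and detection. #3 adds the HR/PR disagreement stage,
configured with a single threshold (`sq_thresh`, studied over
{6, 12, 18} bpm) to produce a binary quality stream that is min-fused with
the SpO2 quality; #4 combines everything. Min-fusion is associative and
commutative, so the fan-in order of the second fusion has no observable
effect. Execution is a topological sort with materialized intermediate
streams; every operator is causal, so the same graphs run sample-at-a-time.

## The synthetic cohort

No public data exist for this setting, so the package ships a seeded
generator whose defaults define the study conditions used throughout the
tests: 11 patients, 4-hour sessions at the native 0.5 Hz (7,200 samples per
stream). Per session:

* SpO2 is integer-rounded AR(1) around 96% (innovation sd 0.5, coefficient
  0.95) — a stable baseline that stays above the monitor's 85% low limit in
  artifact-free operation;
* HR sits near 150 bpm with |PR − HR| bounded by 5 bpm outside events;
* true desaturations (Poisson, 2/h; depth 15–35 pp; 60–180 s) are
  trapezoidal dips — long and deep enough that every formulation should
  find them;
* motion artifacts (6/h; 5–30 s) replace SpO2 with uniform spikes in
  65–100% and decouple PR from HR by 20–60 bpm, with each artifact sample
  tokenized as `"^^"` with probability 0.5 — so half the corruption is
  flagged by the monitor (caught by de-interlacing) and half is unflagged
  numeric corruption (caught only by filtering or sensor fusion);
* sensor-off intervals (1/h; 10–40 s) drop the optical channel to `"NaN"`
  and raise alarm code 5;
* the emulated bedside monitor asserts its alarm on raw threshold
  crossings with no delay and no quality reasoning; its high limit defaults
  to 100% (high alarm disabled, as is common for infants not on
  supplemental oxygen).

Event intervals are mutually disjoint, rates are orders-of-magnitude
choices exposed in `sim_config()` rather than claims about any clinical
population, and one seed determines the cohort byte-for-byte.

What the simulator deliberately does not model: waveform-level signal,
baseline drift and pathology-specific desaturation morphology, correlated
artifact bursts, and monitor averaging behavior. Passing tests therefore
demonstrate that the components implement their contracts and that the
pipeline ordering behaves as designed under these conditions — not that any
particular Sn/FAR level would be attained on real NICU data.

## Evaluation protocol

An alarm episode is true when it overlaps a true desaturation interval
widened by ±10 s (a stand-in for clinician validation criteria that are not
public); each event counts once. Sensitivity is the percentage of events
detected; the false alarm rate is the percentage of issued episodes that
are false, FAR = 100·FP/(TP+FP) — the "what fraction of alarms can the
nurse ignore" reading. Percent changes against a reference monitor are
truncated toward zero at one decimal. Leave-one-patient-out tuning selects,
per fold, the grid point minimizing pooled training FAR subject to training
Sn ≥ a floor (75 or 80%), breaking ties toward the smaller annunciation
delay, then smaller filter window, then smaller disagreement threshold;
fold metrics are averaged unweighted. The default grids are
`ced_dt ∈ {5,10,12,15,20,30,60}`, `med_ww ∈ {5,10,20,25,30,35,60}`,
`sq_thresh ∈ {6,12,18}`.

## Problem sizes used by the test suite

The shipped tests run the full protocol at the study scale — the
11 × 14,400 s cohort through LOOCV for presets #1 and #2 — plus
property-style checks at reduced sizes chosen to exercise every code path:
1,000 random streams of length 600 against a brute-force re-evaluation of
the three alarm conditions, 1,000 random windows against the sort-based
median oracle, closed-form onset over breach depths 1–10 pp × delays
{5,10,20,60} s, and 100 streams for the delay-monotonicity property.

## Known limitations

* The evaluation compares against an emulated, deliberately naive
  threshold-only monitor; absolute Sn/FAR values are properties of the
  simulator, not of any clinical device.
* `ad_fuse_sqi`'s avg on rank streams can produce fractional SQ values;
  downstream components treat any non-zero value as acceptable.
* The detector assumes an SpO2 stream at 1 Hz; other rates require
  re-expressing `ced_dt` and the buffer length in samples.
* `loocv` caches per-patient episode counts per grid point, which assumes
  patients are independent sessions (true of the simulator by
  construction).
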