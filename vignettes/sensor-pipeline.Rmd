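---
title: "Methods: from wearable sensor logs to smoking-behavior events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from wearable sensor logs to smoking-behavior events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokesense)
```

## The problem

Monitoring cigarette smoking in free-living conditions requires fusing
several weak, noisy signals: an instrumented lighter timestamps lighting
events; a wrist module senses the cigarette-to-mouth gesture (inertially
and via an RF link to the chest); a chest module sees the smoke inhalation
itself in two respiration channels (an inductance belt and bioimpedance),
plus ECG, movement and location context. Each device runs on its own clock.
`smokesense` implements this data path — synchronize, denoise, detect,
summarize — together with forward models of every sensor, so that the whole
pipeline can be exercised and validated against known ground truth.

## Sensor forward models

### Respiration belt (RIP)

The belt is the inductor of an LC oscillator, $f_0 = 1/(2\pi\sqrt{LC})$
with $C = 110$ pF (two 220-pF capacitors in series). The microcontroller
counts oscillator pulses per 10-ms window, giving a 100-Hz stream of
counts $\lfloor f_0 \cdot 0.01 \rfloor$; belt inductance grows with the
loop area enclosed by the chest, so counts *fall* on inhalation. The
hardware constraint $f_0 < 16$ MHz (half the 32-MHz system clock) is
enforced as a model error.

$L(c)$ is calibrated from the four breathless bench measurements at
simulated chest circumferences of 60–120 cm (`rip_bench`): each mean count
is converted to $f_0$ and inverted to $L$, and the four $(c, L)$ points are
interpolated with a monotone (Hyman) cubic, extrapolated linearly outside
the calibrated range. An affine $L(c)$ was evaluated first and rejected:
the best least-squares affine law misses the bench counts by up to 0.8%,
whereas the package's invariant is that the calibrated forward model
reproduces all four bench means to within the floor-truncation limit
(≪0.1%). The monotone interpolant also keeps $L$ inside the physical
2–3 µH band and the counts strictly decreasing in circumference.

Breathing modulates circumference as a raised-cosine bump per breath
(amplitude `breath_amplitude_cm` × depth, half-width capped at 45% of the
gap to the neighbouring breath), on a resting baseline equal to the
study-population mean chest circumference (85.63 cm).

### Proximity link

The received signal strength of the 125-kHz wrist-to-chest link is modelled
as $A(d) = 2800 / (1 + (d/4)^3)$ mV. The curve is calibrated to the three
facts known about the hardware: full scale ≈ 2.8 V near contact; at the
typical hand-to-mouth distance (≤ 11 cm) the amplitude stays at least an
order of magnitude above the 7.31-mV receiver noise mean (A(11) ≈ 128 mV >
70 mV); and beyond ~20 cm the signal sinks below the detection threshold
into the noise floor. The exact functional form between these anchors is a
package choice — the hardware characterization is available only as a
plotted curve — and is exposed through `proximity_amplitude_mv()`.

### ECG

A stylized Gaussian R-wave template (σ = 12 ms, 1 mV) is placed at beat
times obtained by integrating the timeline's piecewise-linear heart-rate
profile ($t_{k+1} = t_k + 60/\mathrm{hr}(t_k)$), plus a 60-Hz power-line
sinusoid, slow 0.05-Hz baseline wander, and idle noise. P and T waves are
not modelled because only R-peak timing is consumed downstream. The
heart-rate profile rises from a baseline of 81.5 bpm to 112 bpm during each
cigarette (the study's sitting–smoking mean), drops to 89.7 bpm shortly
after, and returns to baseline within the 15-min recovery window.

### Remaining sensors

Bioimpedance shares the ground-truth breath peak times with RIP (arbitrary
mV scale, idle noise nominally zero). The hand IMU superimposes a large
raised-cosine gesture bump (1.5 g / 200 dps) spanning each puff and smaller
(0.5 g) non-smoking gestures during eating/phone segments, clipped to
±8 g / ±2000 dps; the chest accelerometer adds a 2-Hz walking bounce,
clipped to ±2 g. GPS fixes displace the route by a random distance with the
idle-test mean/sd (15.11 / 2.639 m, uniform bearing) and hold the last
received fix indoors. The pedometer logs step totals per 13.63-s buffer.
The lighter log contains one press/release pair per lighting, optional
repeated strikes, and Poisson spurious presses (default 0.5/day, matching
the order of the study's 19 free-living false events across 40 subjects).

## Clock model

Device time relates to reference time by $t = t_0 + f\,(t_\mathrm{ref} -
t_0)$; compensation inverts it, $t_c = (t - t_0)/f + t_0$, with $f =
(t_\mathrm{device} - t_0)/(t_\mathrm{pc} - t_0)$ from the paired readout at
data extraction. The computer clock is treated as master. Streams carry a
single start time and rate, so compensation corrects the start time and
multiplies the rate by $f$; within-file rate error is absorbed by the same
linear factor. The model is strictly monotone and exactly inverts the
drift-injection used by the generator (round-trip error < 1 ns in tests).
Only a single linear factor per device is supported — temperature-dependent
or piecewise drift is out of scope.

## Conditioning chains

Per sensor: RIP — first-order Butterworth high-pass at 0.1 Hz plus a
10-point Gaussian smoother; bioimpedance — high-pass at 0.001 Hz plus a
100-point smoother; ECG — high-pass at 1 Hz plus a 60-Hz notch; IMU —
second-order low-pass at 2 Hz; proximity — 50-point smoother.

Numerical choices:

- **Zero phase.** All filters are applied forward–backward
  (`signal::filtfilt`). Event timestamps feed cross-sensor comparisons, so
  phase delay must not bias them; a causal first-order 0.1-Hz high-pass
  alone would delay breath peaks by ~1.6 s. Tests verify peak times move
  by ≤ 50 ms.
- **DC removal before high-pass.** The RIP stream rides on a ~95,000-count
  offset; filtering it directly leaves forward–backward edge transients
  that swamp the first/last breaths. The mean (which the high-pass would
  remove anyway) is subtracted first.
- **Single biquad sections.** Every Butterworth stage here has order ≤ 2,
  i.e. one second-order section — numerically robust even for the extreme
  0.001-Hz cutoff on 1-kHz data. The high-pass design is additionally
  checked at construction to null DC to 1e-6.
- **"Average Gaussian filter of N points"** is implemented as convolution
  with a normalized N-tap Gaussian kernel, σ = N/6 (so the kernel is
  effectively supported on its taps), with edge replication; N = 1 is the
  identity. For even N the kernel centre falls between samples, shifting
  the output by half a sample (≤ 5 ms at 100 Hz).
- **Notch quality factor** Q = 30 (bandwidth 2 Hz at 60 Hz): unspecified by
  the chain definition; chosen narrow enough to leave QRS energy intact
  (tests: ≥ 40 dB at 60 Hz, within 1 dB at 10 Hz).

## Event detection

Peak finding is a single primitive (`find_peaks`): strict local maxima
(plateaus contribute their first sample), minimum-distance suppression in
which the highest peaks claim their neighbourhood first, and a topographic
prominence floor. For efficiency on multi-hour 100-Hz streams the
prominence of surviving peaks is evaluated on the peak/valley skeleton
(true sample minima between surviving peaks); in rare configurations a
suppressed intermediate peak can make this an overestimate of strict
topographic prominence, which is acceptable for a floor test.

- **Breaths**: accepted local maxima with ≥ 1-s spacing (caps breathing at
  60/min) and prominence ≥ 10% of the signal IQR. The spacing and
  prominence defaults are package choices — the reduction step is defined
  only as local-maxima finding. RIP streams are inverted first (counts dip
  on inhalation).
- **R-peaks**: maxima with a 0.3-s refractory interval and a height floor
  of half the median-to-99.9th-percentile span. Instantaneous HR is 60/RR
  assigned to the interval midpoint: the natural, window-length-independent
  reading of "R-peaks per minute". Windows with fewer than two peaks raise
  an error rather than returning a silent zero. The session summary
  averages instantaneous HR over the session, the 5 min before and the
  15 min after.
- **Proximity**: maximal runs above 70 mV (= 10 × the 7-mV noise mean),
  runs closer than 0.5 s merged. Raising the threshold can only reduce the
  event count (tested).
- **Lighter consolidation**: presses inside a self-reported session or
  within 60 s before its start belong to it; within a session, presses
  separated by more than the merge window count as separate lightings, so
  a session covering several cigarettes still yields several estimates.
  Unassigned presses are discarded but reported as false lighting events;
  conservation (grouped + discarded = total) is a tested invariant. Both
  raw press counts and consolidated counts are reported, since self-reports
  merging several cigarettes into one session cannot be disambiguated.
- **Usability**: 60-s windows; a window is `removed` when both respiration
  channels fall below their flatline floors (3× the RIP idle-noise sd;
  0.01 mV absolute for bioimpedance, whose nominal idle noise is zero),
  `ambiguous` when exactly one does.
- **IMU gestures**: the hand-to-mouth gesture classifier is deliberately a
  pluggable interface; the shipped default is a documented
  threshold-crossing placeholder (|deviation from median| > 1 g, 1-s
  merge), adequate only for clean synthetic renders.

## Summaries

The study report mirrors the per-portion bookkeeping (controlled,
free-living, total; totals are sums by construction) and computes the
breath-count agreement as (RIP − bioimpedance)/RIP × 100 — the belt is the
reference sensor; on the shipped study counts this is 1.7878%, displayed
as 1.78% under the same truncate-to-2-decimals convention the bench
frequency column uses (`count_to_mhz` encodes truncation, verified against
all four bench rows). Cross-correlation is maximized over lags after mean
removal, normalized by the overlap energies so an exact shifted copy scores
1.0; zero-lag Pearson is available via `max_lag = 0`. Distances use the
spherical haversine with R = 6,371 km; displacement of a track is measured
to the nearest reference-route vertex.

## What the generator does and does not emulate

It emulates: bench noise levels of every sensor, the RIP bench calibration,
smoking sessions with in-reach puffs and characteristic deep inhalation
amplitudes, heart-rate elevation with post-smoking recovery, spurious
lighter activity, walking/steps/routes with indoor GPS holds, and
per-device clock drift. A fixed seed makes every render bit-reproducible
(per-render substreams are derived deterministically from the scenario
seed).

It does not emulate: real motion artifacts (the conditioning chains face
only stationary Gaussian noise), a biomechanical arm model or realistic
IMU gesture morphology, RF multipath, ECG morphology beyond the R wave, or
sensor degradation over wear time. Passing recovery tests therefore shows
the pipeline is correct and self-consistent, not that its default
parameters are optimal on real recordings.

## Problem sizes and runtime choices

Simulations in the tests are sized to keep the default suite in the
few-minute range while still exercising every stage at scale: the
end-to-end recovery test uses a full 24-h subject with the 100-Hz streams
(RIP, proximity, IMU) rendered for the whole day, while the 1-kHz streams
(ECG, bioimpedance) are rendered for analysis windows around a smoking
session — a full-day 1-kHz render is ~86M samples and adds nothing to the
windowed analysis, because beat times are integrated from the scenario
start regardless of the rendered window. Sensor-agreement and bench checks
use 1–60-min fixtures.

## Known limitations

- The on-disk formats are inspectable delimited text, not the original
  binary SD-card records, whose layout is undocumented.
- The affine-vs-interpolated $L(c)$ choice matters only inside 60–120 cm;
  extrapolation beyond the calibrated range is linear and unvalidated.
- `screen_usability` labels at window resolution (60 s), so removal
  intervals are detected to within one window.
- The IMU gesture count is a placeholder interface, not a validated
  classifier.
- Cross-correlation against spirometer maneuvers is provided as the
  generic `xcorr_coefficient`; no spirometer forward model ships.
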