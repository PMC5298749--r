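---
title: "Methods: vital-sign estimation, packet protection and network simulation in bsnkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vital-sign estimation, packet protection and network simulation in bsnkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsnkit)
```

bsnkit is a software re-creation of a hospital remote-monitoring stack
built around a wearable sensor node and a fixed bedside measurement
station, both reporting through a hierarchical low-power wireless
sensor network. The hardware is replaced by synthetic signal
generators with known ground truth, so every estimator, codec and
network behaviour is testable on a desk. This vignette explains the
models behind each component, the parameters that matter, and the
design decisions taken where the original system left them open.

## Synthetic signals and what they do (not) emulate

Each generator takes an explicit `seed` and returns both the signal and
a `ground_truth` object holding the generating parameters, making
generator→estimator round trips the package's central testing contract.

**ECG.** `gen_ecg()` repeats a fixed single-beat template at the
requested rate: a small P bump, a sharp R spike with a slow cubic
upstroke and a steep RS downstroke, a linear S recovery, and a T bump.
The template is deliberately minimal — only the R-ridge *timing*
carries information for the rate algorithm, which averages
ridge-to-ridge intervals. The downstroke is the steepest segment and
begins exactly at the ridge sample, which pins the maximum of the
absolute first difference (the detector's statistic) to the ridge. The
default sampling rate is 250 Hz, the rate the wearable node itself
uses. RR jitter is uniform per interval (`±jitter_frac`), and beat
positions are rounded once after accumulation so a jitter-free signal
has bit-exact integer spacing.

**PPG.** `gen_ppg()` produces a red and an infrared channel, each a DC
perfusion level plus a sinusoidal pulsatile component at the cardiac
frequency. The infrared perfusion (AC/DC) is fixed at 5 %, a typical
fingertip value; the red perfusion is scaled so that the ratio of
ratios equals the value the calibration line maps back to the requested
saturation.

**Respiration, accelerometer, RTD bridge.** The airflow signal is a
unit sinusoid at the breath frequency. The four accelerometer
scenarios (`stand`, `walk`, `lie`, `fall`) have separable gravity
signatures; the fall timeline is 1.5 s standing, 0.25 s of near-zero
magnitude (free fall), a 0.06 s impact spike of ≈3.2 g, then lying
still. The RTD generator computes the Wheatstone-bridge output for a
linear PT100 element and is the exact algebraic inverse of the
temperature estimator.

None of the generators model pathology, motion artifacts or sensor
drift, and the PPG has no respiratory or movement modulation. A passing
round-trip therefore demonstrates that the estimator implements its
stated rule correctly — not that it is robust to clinical-grade signal
corruption.

## Vital-sign estimators

**QRS detection and heart rate.** The detector buffers `buffer_n`
samples (default 1000 — four seconds at 250 Hz), computes the absolute
first difference, thresholds it at `derivative_threshold_frac` of the
in-window maximum, and scans left to right, marking a ridge wherever
the difference exceeds the threshold and then ignoring the next 50
samples so one complex is never counted twice. The threshold fraction
(default 0.5) is a design decision: the original description thresholds
the derivative but never states the level, and a per-window fraction of
the maximum adapts automatically to amplifier gain. Two windowing
choices matter:

* the derivative of each window extends one sample into the next
  buffer, so a complex sitting exactly on a window boundary still
  contributes its steep difference;
* the refractory skip carries across the boundary, so a complex
  detected at the end of one window cannot re-fire at the start of the
  next.

Heart rate is then `60 · fs / RR_avg` with `RR_avg` the mean
ridge-to-ridge spacing in samples — the estimate and the averaged
interval satisfy this identity to within one double-precision ulp by
construction.

**Respiration.** Breath onsets are upward crossings of a threshold
placed at `threshold_frac` (default 0.5) of the peak-to-peak range
above the minimum; the rate is 60 over the mean inter-onset time.
Fewer than two crossings is an error, not a zero.

**Pulse oximetry.** Per channel, DC is the mean and AC the
peak-to-peak range of the mean-removed signal; saturation is the
conventional empirical line `SpO2 = 110 − 25·R` clamped to [0, 100].
The optical front-end's factory calibration is proprietary, so the line
is exposed as configuration (`spo2_calibration()`); the generator
inverts the same line, which makes the round trip — not the absolute
calibration — the tested contract.

**Temperature.** A PT100 in a quarter bridge of equal 100 Ω arms with
3.3 V excitation, inverted analytically; the linear Callendar–Van Dusen
approximation (α = 0.00385 /°C) is accurate to well under 0.01 °C
across the clinical range relative to its own model, and the
manufacturer's proprietary linearization is intentionally not
reproduced.

**Fall detection.** Three stages within a short horizon: magnitude
below 0.4 g for at least 60 ms (free fall), a sample above 2.5 g within
0.5 s (impact), then horizontal orientation (|x| or |y| dominating |z|)
sustained for 1 s after a 0.2 s settling gap, with the pre-fall posture
vertical. All thresholds are configurable in `fall_config()`; the
defaults are co-designed with `gen_accel()` so the four labeled
scenarios are separable. A slow, controlled lie-down has neither free
fall nor impact and raises nothing.

## Packet formats and payload protection

The three wire messages carry the field lists of the platform's tables;
the original specification gives abstract column types but no widths or
byte order, so the package declares its wire dialect explicitly: a
1-byte type tag, then little-endian int32 identifiers, IEEE-754 float32
reals, an int16 respiration rate, and temperature as int32
centi-degrees (the table calls for an integer; hundredths preserve the
two decimals a body thermometer reports). Encoded sizes are constant —
19, 25 and 329 bytes — so framing is unambiguous from tag plus length.
Constructors snap float fields to their float32 representation, making
`decode(encode(p))` an exact identity rather than an approximate one.

Payload protection is AES-128 in CTR mode (through OpenSSL) with a
fresh 16-byte nonce prepended per packet; CTR was chosen because it
needs no padding on short radio frames and tolerates bit slips without
error propagation. CBC with PKCS#7 padding is provided as the
alternative mode. Key distribution is a static pre-shared key; no key
exchange is modeled.

## Network simulation

The simulator is a slotted event loop over a generated traffic
schedule. Radio reach uses log-distance path loss
(`rssi = tx − (L0 + 10·n·log10 d)`, defaults `L0 = 40 dB`, `n = 2`)
with optional Gaussian shadowing; a link exists when the deterministic
RSSI clears the receiver sensitivity. `range_to_sensitivity()` converts
a wanted radio range into the sensitivity that realizes it, which is
how "a 10 m range" is expressed throughout the package.

Routing follows the hierarchical design: hop counts are breadth-first
distances from the single sink, remote nodes are leaves that originate
traffic but never relay, and every in-range neighbour strictly closer
to the sink is kept as a routing entry — the redundancy that lets
delivery survive a relay failure. Entries are ordered by a link weight
combining the three stated ingredients, each normalized to [0, 1] over
declared ranges: `w = 0.5·norm(rssi) − 0.3·norm(hops) + 0.2·norm(ttl)`.
The original description names RSSI, hop count and node lifetime (TTL)
as the metric's inputs but not their combination; a linear weighted sum
of normalized terms is the simplest form monotone in each, and the
weights are configurable. TTL is a battery-proxy counter decremented
per transmission; weights are refreshed whenever the topology changes
(a failure or rejoin), not per packet.

Medium access is an abstraction of CSMA/CA, not the full IEEE 802.15.4
MAC: transmissions claim absolute 10 ms slots; a sender finding its
slot busy backs off a uniform number of slots and retries, and is
dropped after `retry_limit` collisions. An independent per-hop
`loss_floor` models residual channel loss. When a packet's best next
hop is dead it falls back to the next routing entry at send time; a
rejoining node triggers a route rebuild and adopts a role by the
reduced election rule (cluster if a remote node is in range, else
gateway). Accounting is exact: `generated = delivered + lost` in every
run and `loss_pct = 100·lost/generated`. `run_simulation()` also
accepts an explicit drop schedule — deliberate loss injection used to
validate the accounting path against known totals.

Only the continuous (proactive) reporting scheme is simulated; the
reactive scheme reduces to a different traffic schedule and is not a
separate mode.

## Centroid localization

`estimate_position()` implements the classic range-free centroid — the
arithmetic mean of the anchors that hear the node — with an
RSSI-weighted variant (weights `10^(rssi/10)`, i.e. linearized received
power) for comparison; plain is the default. The accuracy fixture is a
4×3 anchor grid at the cell centers of the 27 m × 17 m pilot floor,
the printed test-area dimensions; the original floor plan's exact
anchor coordinates are not recoverable, so a uniform grid is the
declared stand-in. `evaluate_localization()` samples positions
uniformly, derives in-range anchors from the deterministic channel, and
reports mean and maximum Euclidean error plus coverage. With a 10 m
radio range over that grid the mean plain-centroid error is about
3.3 m, comfortably inside the 7.6 m accuracy the deployed system
reported, and adding anchors can only refine it (the paired-seed
monotonicity property in the test suite).

## Alerts and records

`check_record()` compares each measurement present in a record against
per-measurement [min, max] ranges; a set fall flag always alerts
regardless of ranges. The shipped defaults (36–38 °C, 60–100 bpm,
94–100 % SpO2, 12–20 breaths/min) are conventional adult resting
ranges — the platform left them to the clinician, and every bound is
overridable per patient. Vendor push delivery is out of scope; alerts
go to a JSON-lines log with wall-clock stamps so pipeline latency is
measurable without third-party notification servers. Records serialize
to canonical JSON with fixed key order, ISO-8601 UTC timestamps
(millisecond resolution, which the record constructor also enforces so
the round trip is exact), and absent fields omitted rather than
null-filled.

## The pilot scenario

`run_pilot()` wires everything together at the deployment's scale: 12
communication nodes (5 cluster, 6 gateway, 1 sink — the sink at the
grid position nearest the floor center) over 27 m × 17 m, one remote
node visiting 16 rooms with a 3-minute dwell over 60 minutes,
continuous packets at 1 Hz plus an ECG packet every 1.25 s, and a fixed
station reporting at 1 Hz for its 3-minute session (exactly 180
packets). The observed pilot total of 6650 packets in an hour implies
≈1.85 packets/s without stating a split; the default 1 Hz + 0.8 Hz mix
(6480 packets/h) is the package's choice and any total is reproducible
by configuration. The remote node's packets are serialized with a
5-slot minimum gap — one radio cannot transmit two packets in the same
slot — and the node is re-placed (with a route rebuild) per room rather
than continuously, a granularity consistent with per-room dwells.
Per-minute vitals records are estimated from freshly generated signals;
two anomalies can be injected to exercise the alert path: a 30 °C
temperature reading (a cold object on the sensor) and one deliberate
fall.

## Problem sizes and numerical choices

The test suite and the acceptance script run at the scales the methods
themselves call for: 1000-position localization sweeps, 15-rate
heart-rate sweeps on 20 s records, 200 randomized detector windows up
to 2000 samples, 1000 randomized packet round trips, and scaled-down
(4-room / 20-minute) pilots where the full hour adds nothing to the
property under test. The full 60-minute pilot runs in about a second.

Degenerate inputs are errors, not silent values: a flat ECG window
yields an empty annotation (the one case where "nothing" is the right
answer), but a constant respiration signal, a single R ridge, zero PPG
perfusion, a full-scale GSR reading and a bridge voltage outside the
reachable range all raise conditions with descriptive messages.
Ties in the derivative scan are resolved left to right; the detector
marks the first sample whose difference exceeds the threshold.

## Known limitations

* Generators are idealized; no arrhythmia, apnea, artifact or drift.
* The MAC model is abstract: no acknowledgements, hidden terminals or
  capture effect, and contention is slot-exact rather than
  airtime-accurate.
* Mobility is piecewise static (per-room), not continuous.
* The SpO2 line and the fall thresholds are conventional defaults, not
  device calibrations; absolute accuracy against hardware is untested
  by construction.
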