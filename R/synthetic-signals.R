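# Synthetic physiological signals with known ground truth.
#
# Every generator takes an explicit `seed` and is bit-for-bit reproducible;
# the generated parameters are returned as ground truth so the estimators
# in vitals.R can be scored without hardware.

# Continuous single-beat ECG template, evaluated at offsets `dt` (seconds)
# relative to the R ridge. Morphology is deliberately minimal: a small P
# bump, a sharp asymmetric R spike (slow cubic upstroke, steep RS
# downstroke starting exactly at the ridge), a linear S recovery and a T
# bump. Only the ridge timing carries information; the steep downstroke
# pins the maximum of the absolute first difference to the ridge sample,
# which is the fiducial the derivative-threshold detector marks.
ecg_beat_template <- function(dt) {
  v <- numeric(length(dt))
  v <- v + 0.15 * exp(-((dt + 0.20) / 0.025)^2 / 2)        # P
  ris <- dt >= -0.02 & dt <= 0
  v[ris] <- v[ris] + ((dt[ris] + 0.02) / 0.02)^3           # R upstroke
  fall <- dt > 0 & dt <= 0.004
  v[fall] <- v[fall] + 1 - 1.4 * dt[fall] / 0.004          # RS downstroke
  rec <- dt > 0.004 & dt <= 0.04
  v[rec] <- v[rec] - 0.4 * (1 - (dt[rec] - 0.004) / 0.036) # S recovery
  v + 0.30 * exp(-((dt - 0.30) / 0.05)^2 / 2)              # T
}

#' Generate a synthetic single-lead ECG with known R-ridge positions
#'
#' Builds an ECG as a fixed beat template repeated with mean RR interval
#' `60 * fs / hr_bpm` samples, optionally jittered beat-to-beat, plus
#' additive Gaussian noise. The true R-ridge sample indices are returned
#' as ground truth.
#'
#' @param hr_bpm Target heart rate, beats per minute (20--250).
#' @param duration_s Signal duration, seconds (must exceed two beats).
#' @param fs Sampling rate in Hz (>= 100); default 250, the rate the
#'   wearable node samples at.
#' @param noise_sd Standard deviation of additive Gaussian noise, in
#'   units of the R-ridge amplitude (1.0).
#' @param jitter_frac Each RR interval is scaled by a factor drawn
#'   uniformly from `1 +/- jitter_frac`; must be < 0.5.
#' @param seed Integer seed; `NULL` uses (and advances) the global RNG.
#' @return A list with `waveform` and `truth` (`ground_truth` whose
#'   `event_indices` are the R-ridge samples and whose `scalar_params`
#'   record `hr_bpm`).
#' @examples
#' ecg <- gen_ecg(60, duration_s = 10, fs = 250, seed = 1)
#' diff(ecg$truth$event_indices)  # exactly 250 samples at 60 bpm
#' @export
gen_ecg <- function(hr_bpm, duration_s, fs = 250, noise_sd = 0,
                    jitter_frac = 0, seed = NULL) {
  stopifnot(hr_bpm >= 20, hr_bpm <= 250, fs >= 100, noise_sd >= 0,
            jitter_frac >= 0)
  if (duration_s <= 2 * 60 / hr_bpm)
    stop("duration_s must exceed two beat periods")
  if (jitter_frac >= 0.5)
    stop("jitter_frac must be < 0.5 (RR interval could collapse)")
  n <- round(duration_s * fs)
  rr <- 60 * fs / hr_bpm
  with_seed(seed, {
    # beat centers: cumulative jittered RR, rounded once at the end so a
    # jitter-free signal has bit-exact integer spacing
    max_beats <- ceiling(n / rr) + 2L
    scale <- if (jitter_frac > 0)
      1 + runif(max_beats, -jitter_frac, jitter_frac) else rep(1, max_beats)
    centers <- round(0.4 * fs) + c(0, cumsum(rr * scale[-max_beats]))
    centers <- round(centers)
    centers <- centers[centers <= n - round(0.1 * fs)]
    s <- numeric(n)
    half <- round(0.45 * fs)
    for (c0 in centers) {
      idx <- max(1L, c0 - half):min(n, c0 + half)
      s[idx] <- s[idx] + ecg_beat_template((idx - c0) / fs)
    }
    if (noise_sd > 0) s <- s + rnorm(n, sd = noise_sd)
    list(waveform = waveform(s, fs, units = "mV"),
         truth = ground_truth(centers,
                              list(hr_bpm = hr_bpm, fs = fs),
                              n_samples = n))
  })
}

#' Generate a dual-wavelength photoplethysmogram for a target SpO2
#'
#' Each channel is a DC perfusion baseline plus a pulsatile component at
#' the cardiac frequency. The AC/DC amplitudes are chosen so that the
#' ratio of ratios `R = (AC_red/DC_red) / (AC_ir/DC_ir)` equals the value
#' that the default calibration line (see [estimate_spo2()]) maps back to
#' `spo2_pct`, making generator -> estimator a round trip.
#'
#' @param spo2_pct Target oxygen saturation, percent (70--100).
#' @param hr_bpm Cardiac frequency driving the pulsatile component.
#' @param duration_s,fs Signal duration (s) and sampling rate (Hz).
#' @param seed Integer seed (randomizes the pulse phase).
#' @param cal Calibration line, as from [spo2_calibration()].
#' @return A list with `ppg` (a [dual_ppg()]) and `truth`.
#' @export
gen_ppg <- function(spo2_pct, hr_bpm = 75, duration_s = 10, fs = 100,
                    seed = NULL, cal = spo2_calibration()) {
  if (spo2_pct < 70 || spo2_pct > 100)
    stop("spo2_pct must lie in [70, 100]")
  stopifnot(duration_s * hr_bpm / 60 >= 2, fs > 2 * hr_bpm / 60)
  r_target <- (cal$intercept - spo2_pct) / cal$slope
  with_seed(seed, {
    t <- seq(0, by = 1 / fs, length.out = round(duration_s * fs))
    phase <- runif(1, 0, 2 * pi)
    pulse <- sin(2 * pi * hr_bpm / 60 * t + phase)
    dc_ir <- 1.0; perf_ir <- 0.05        # AC(peak-to-peak)/DC of the IR channel
    dc_red <- 0.9; perf_red <- r_target * perf_ir
    ir  <- waveform(dc_ir  + dc_ir  * perf_ir  / 2 * pulse, fs, "adu")
    red <- waveform(dc_red + dc_red * perf_red / 2 * pulse, fs, "adu")
    list(ppg = dual_ppg(red, ir),
         truth = ground_truth(scalar_params = list(spo2_pct = spo2_pct,
                                                   hr_bpm = hr_bpm,
                                                   ratio = r_target)))
  })
}

#' Generate a synthetic airflow (respiration) signal
#'
#' A sinusoid at the breath frequency plus Gaussian noise. Breath onsets
#' (upward mid-range crossings) are returned as ground truth.
#'
#' @param rr_bpm True respiration rate, breaths per minute (4--60).
#' @param duration_s,fs Duration (s) and sampling rate (Hz).
#' @param noise_sd Additive Gaussian noise sd (signal amplitude is 1).
#' @param seed Integer seed.
#' @return A list with `waveform` and `truth` (onset indices,
#'   `rr_bpm`).
#' @export
gen_respiration <- function(rr_bpm, duration_s = 60, fs = 25,
                            noise_sd = 0, seed = NULL) {
  if (rr_bpm < 4 || rr_bpm > 60)
    stop("rr_bpm outside the physiological range [4, 60]")
  stopifnot(duration_s > 2 * 60 / rr_bpm, fs > 0, noise_sd >= 0)
  n <- round(duration_s * fs)
  with_seed(seed, {
    t <- (seq_len(n) - 1) / fs
    s <- sin(2 * pi * rr_bpm / 60 * t)
    if (noise_sd > 0) s <- s + rnorm(n, sd = noise_sd)
    period <- 60 / rr_bpm
    onsets <- round(seq(0, duration_s - period, by = period) * fs) + 1L
    list(waveform = waveform(s, fs, units = "L/min"),
         truth = ground_truth(onsets, list(rr_bpm = rr_bpm),
                              n_samples = n))
  })
}

#' Generate a tri-axial accelerometer scenario
#'
#' Four labeled scenarios with separable signatures for the three-stage
#' fall detector: `stand` (gravity on z), `lie` (gravity on x), `walk`
#' (gravity on z plus periodic gait bursts), and `fall` (standing, then a
#' free-fall segment of near-zero magnitude, an impact spike, and
#' sustained horizontal orientation).
#'
#' @param scenario One of `"stand"`, `"walk"`, `"lie"`, `"fall"`.
#' @param duration_s Duration in seconds (>= 4 for `"fall"`).
#' @param fs Sampling rate in Hz (>= 20).
#' @param seed Integer seed.
#' @return An [accel_trace()] with `scenario_label` set.
#' @export
gen_accel <- function(scenario, duration_s = 8, fs = 50, seed = NULL) {
  scenario <- match.arg(scenario, c("stand", "walk", "lie", "fall"))
  stopifnot(fs >= 20, duration_s >= 2)
  if (scenario == "fall" && duration_s < 4)
    stop("fall scenario needs duration_s >= 4")
  n <- round(duration_s * fs)
  with_seed(seed, {
    t <- (seq_len(n) - 1) / fs
    jit <- function(sd = 0.02) rnorm(n, sd = sd)
    x <- jit(); y <- jit(); z <- jit()
    if (scenario == "stand") {
      z <- z + 1
    } else if (scenario == "lie") {
      x <- x + 1
    } else if (scenario == "walk") {
      z <- z + 1 + 0.25 * sin(2 * pi * 2 * t)
      x <- x + 0.10 * sin(2 * pi * 2 * t + pi / 3)
    } else { # fall: stand -> free fall -> impact -> lying
      i_ff  <- t >= 1.5 & t < 1.75
      i_imp <- t >= 1.75 & t < 1.75 + 0.06
      i_lie <- t >= 1.75 + 0.06
      z[t < 1.5] <- z[t < 1.5] + 1
      x[i_ff] <- rnorm(sum(i_ff), sd = 0.05)
      y[i_ff] <- rnorm(sum(i_ff), sd = 0.05)
      z[i_ff] <- rnorm(sum(i_ff), sd = 0.05)
      x[i_imp] <- x[i_imp] + 3.2
      x[i_lie] <- x[i_lie] + 1
    }
    accel_trace(x, y, z, fs, scenario_label = scenario)
  })
}

#' RTD Wheatstone-bridge output voltage for a given temperature
#'
#' Computes the RTD resistance from the linear model
#' `R(T) = r0 * (1 + alpha * T)` and the differential output of the
#' Wheatstone bridge it sits in; the exact inverse of
#' [body_temperature()].
#'
#' @param temp_c Temperature in degrees Celsius (-10 to 60).
#' @param bridge A [bridge_config()].
#' @return Bridge output voltage in volts.
#' @examples
#' gen_rtd_voltage(0)   # balanced bridge -> 0 V
#' body_temperature(gen_rtd_voltage(37), bridge_config())  # 37
#' @export
gen_rtd_voltage <- function(temp_c, bridge = bridge_config()) {
  if (temp_c < -10 || temp_c > 60)
    stop("temp_c outside the supported range [-10, 60] degC")
  r_rtd <- bridge$r0 * (1 + bridge$alpha * temp_c)
  r <- bridge$bridge_resistors
  bridge$excitation_v * (r_rtd / (r_rtd + r[1]) - r[3] / (r[2] + r[3]))
}
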