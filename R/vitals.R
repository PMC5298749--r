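# Vital-sign estimation algorithms of the monitoring stack: QRS/heart
# rate from the first-derivative rule, threshold-crossing respiration
# rate, ratio-of-ratios pulse oximetry, Wheatstone-bridge temperature,
# GSR resistance and three-stage accelerometer fall detection.

#' QRS detector configuration
#'
#' The wearable node buffers `buffer_n` samples (1000 by default), takes
#' the absolute first derivative, thresholds it at a fraction of the
#' in-window maximum, and ignores the `refractory` samples (50 by
#' default) after each detection so one complex is never counted twice.
#'
#' @param buffer_n Samples per processing window (> 2 * refractory).
#' @param refractory Post-detection skip length, samples.
#' @param derivative_threshold_frac Fraction of the in-window maximum
#'   absolute derivative used as detection threshold, in (0, 1).
#' @param fs Sampling rate in Hz.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(buffer_n = 1000L, refractory = 50L,
                            derivative_threshold_frac = 0.5, fs = 250) {
  stopifnot(buffer_n > 2 * refractory, refractory >= 0,
            derivative_threshold_frac > 0, derivative_threshold_frac < 1,
            fs > 0)
  structure(list(buffer_n = as.integer(buffer_n),
                 refractory = as.integer(refractory),
                 derivative_threshold_frac = derivative_threshold_frac,
                 fs = as.numeric(fs)),
            class = "detector_config")
}

#' Detect QRS complexes by thresholding the absolute first derivative
#'
#' Processes the ECG in consecutive `buffer_n`-sample windows. Within
#' each window the absolute first difference `d[i] = |s[i+1] - s[i]|` is
#' computed, the threshold set to `derivative_threshold_frac * max(d)`,
#' and the window scanned left to right: each sample where `d` exceeds
#' the threshold is marked as an R ridge and the following `refractory`
#' samples are skipped. The skip state carries across window boundaries
#' so a complex straddling two windows is not double-counted. A final
#' partial window is processed if it spans at least 2 s.
#'
#' @param ecg A [waveform()].
#' @param cfg A [detector_config()]; its `fs` is overridden by the
#'   waveform's sampling rate.
#' @return An object of class `qrs_annotation`: list with `r_indices`
#'   (1-based sample indices, strictly increasing) and `fs`.
#' @export
detect_qrs <- function(ecg, cfg = detector_config()) {
  stopifnot(inherits(ecg, "waveform"), inherits(cfg, "detector_config"))
  s <- ecg$samples
  n <- length(s)
  if (n < cfg$buffer_n)
    stop("signal shorter than one detector buffer (", cfg$buffer_n,
         " samples)")
  starts <- seq(1L, n, by = cfg$buffer_n)
  marks <- integer(0)
  skip_carry <- 0L           # refractory remainder carried into next window
  for (w0 in starts) {
    w1 <- min(w0 + cfg$buffer_n - 1L, n)
    if (w1 - w0 + 1L < 2 * ecg$fs && w0 > 1L) break   # short tail dropped
    # the derivative spans one sample into the next buffer so a complex
    # sitting exactly on the boundary still produces its difference
    d <- abs(diff(s[w0:min(w1 + 1L, n)]))
    if (length(d) == 0L) break
    thr <- cfg$derivative_threshold_frac * max(d)
    if (max(d) == 0) { skip_carry <- 0L; next }       # flat window
    i <- 1L + skip_carry
    m <- length(d)
    while (i <= m) {
      if (d[i] > thr) {
        marks <- c(marks, w0 + i - 1L)
        i <- i + 1L + cfg$refractory
      } else i <- i + 1L
    }
    skip_carry <- max(0L, i - m - 1L)
  }
  structure(list(r_indices = as.integer(marks), fs = ecg$fs),
            class = "qrs_annotation")
}

#' Heart rate from averaged RR intervals
#'
#' Implements the node's rate equation: the RR intervals between
#' consecutive detected R ridges are averaged and the heart rate is
#' `60 * fs / RR_avg` beats per minute (with `fs = 250` Hz on the
#' device).
#'
#' @param ann A `qrs_annotation` from [detect_qrs()] with at least two
#'   ridges.
#' @return An object of class `heart_rate_estimate`: list with `hr_bpm`
#'   and `rr_avg_interval` (samples); `hr_bpm * rr_avg_interval ==
#'   60 * fs` exactly.
#' @examples
#' ann <- structure(list(r_indices = c(1L, 251L, 501L), fs = 250),
#'                  class = "qrs_annotation")
#' heart_rate(ann)$hr_bpm  # 60
#' @export
heart_rate <- function(ann) {
  stopifnot(inherits(ann, "qrs_annotation"))
  if (length(ann$r_indices) < 2L)
    stop("need at least two R ridges to form an RR interval")
  rr_avg <- mean(diff(ann$r_indices))
  structure(list(hr_bpm = 60 * ann$fs / rr_avg,
                 rr_avg_interval = rr_avg),
            class = "heart_rate_estimate")
}

#' Respiration rate from threshold crossings
#'
#' The station measures the duration of single breaths and extrapolates
#' breaths per minute: a threshold is placed a fraction of the
#' peak-to-peak range above the signal minimum, breath onsets are the
#' upward crossings of that threshold, and the rate is 60 divided by the
#' mean inter-onset time.
#'
#' @param resp A [waveform()] spanning at least two breaths.
#' @param threshold_frac Threshold position within the peak-to-peak
#'   range, in (0, 1).
#' @return Respiration rate in breaths per minute.
#' @export
respiration_rate <- function(resp, threshold_frac = 0.5) {
  stopifnot(inherits(resp, "waveform"),
            threshold_frac > 0, threshold_frac < 1)
  s <- resp$samples
  rng <- range(s)
  if (diff(rng) == 0) stop("constant signal: no breath crossings")
  thr <- rng[1] + threshold_frac * diff(rng)
  up <- which(s[-length(s)] <= thr & s[-1] > thr) + 1L
  if (length(up) < 2L)
    stop("fewer than two threshold crossings: rate unmeasurable")
  60 / mean(diff(up) / resp$fs)
}

#' SpO2 calibration line
#'
#' The empirical pulse-oximetry line `SpO2 = intercept - slope * R`
#' mapping the ratio of ratios R to oxygen saturation. The optical
#' front-end's factory calibration is proprietary; the conventional
#' linear approximation is used and both coefficients are exposed.
#'
#' @param intercept,slope Calibration coefficients (percent, percent per
#'   unit R).
#' @return A list with `intercept` and `slope`.
#' @export
spo2_calibration <- function(intercept = 110, slope = 25) {
  stopifnot(slope > 0)
  list(intercept = intercept, slope = slope)
}

#' Estimate SpO2 from a dual-wavelength photoplethysmogram
#'
#' Per channel the DC level is the signal mean and the AC amplitude the
#' peak-to-peak range of the mean-removed signal; the ratio of ratios
#' `R = (AC_red/DC_red) / (AC_ir/DC_ir)` is mapped through the
#' calibration line and clamped to \[0, 100\].
#'
#' @param ppg A [dual_ppg()] spanning at least two cardiac cycles.
#' @param cal Calibration from [spo2_calibration()].
#' @return Estimated SpO2 in percent.
#' @export
estimate_spo2 <- function(ppg, cal = spo2_calibration()) {
  stopifnot(inherits(ppg, "dual_ppg"))
  chan <- function(w) {
    dc <- mean(w$samples)
    ac <- diff(range(w$samples - dc))
    list(dc = dc, ac = ac)
  }
  red <- chan(ppg$red); ir <- chan(ppg$ir)
  if (red$dc <= 0 || ir$dc <= 0)
    stop("non-positive DC level: no perfusion signal")
  if (ir$ac == 0) stop("zero IR pulsation: ratio undefined")
  r <- (red$ac / red$dc) / (ir$ac / ir$dc)
  min(100, max(0, cal$intercept - cal$slope * r))
}

#' Wheatstone bridge configuration for the RTD temperature channel
#'
#' Defaults describe a PT100 element (`r0` = 100 ohm at 0 degC, alpha =
#' 0.00385 per degC, the linear Callendar-Van Dusen approximation) in a
#' quarter bridge of equal 100-ohm completion resistors.
#'
#' @param r0 RTD resistance at 0 degC, ohms.
#' @param alpha Linear temperature coefficient, 1/degC.
#' @param bridge_resistors The three completion resistors (r1 in series
#'   with the RTD; r2, r3 forming the reference divider), ohms.
#' @param excitation_v Bridge excitation voltage, volts.
#' @return An object of class `bridge_config`.
#' @export
bridge_config <- function(r0 = 100, alpha = 0.00385,
                          bridge_resistors = c(100, 100, 100),
                          excitation_v = 3.3) {
  stopifnot(r0 > 0, alpha > 0, length(bridge_resistors) == 3,
            all(bridge_resistors > 0), excitation_v > 0)
  structure(list(r0 = r0, alpha = alpha,
                 bridge_resistors = as.numeric(bridge_resistors),
                 excitation_v = excitation_v),
            class = "bridge_config")
}

#' Body temperature from the RTD bridge voltage
#'
#' Inverts the Wheatstone bridge equation to recover the RTD resistance,
#' then applies the linear RTD model `T = (R/r0 - 1) / alpha`. Exact
#' inverse of [gen_rtd_voltage()].
#'
#' @param bridge_v Measured bridge output voltage, volts.
#' @param bridge A [bridge_config()].
#' @return Temperature in degrees Celsius.
#' @export
body_temperature <- function(bridge_v, bridge = bridge_config()) {
  stopifnot(inherits(bridge, "bridge_config"))
  r <- bridge$bridge_resistors
  a <- bridge_v / bridge$excitation_v + r[3] / (r[2] + r[3])
  if (a >= 1 || a <= 0)
    stop("bridge voltage outside the reachable range")
  r_rtd <- a * r[1] / (1 - a)
  (r_rtd / bridge$r0 - 1) / bridge$alpha
}

#' Skin resistance from a GSR ADC reading
#'
#' The galvanic channel digitizes the voltage across the skin in a
#' divider against `divider_r`: `v = counts * vref / (2^bits - 1)`,
#' `R_skin = divider_r * v / (vref - v)`.
#'
#' @param adc_counts Raw ADC reading, `0 <= counts < 2^adc_bits`.
#' @param adc_bits ADC resolution in bits (10 on the device).
#' @param vref ADC reference voltage, volts.
#' @param divider_r Fixed divider resistor, ohms.
#' @return Skin resistance in ohms.
#' @export
gsr_resistance <- function(adc_counts, adc_bits = 10L, vref = 3.3,
                           divider_r = 1e5) {
  full <- 2^adc_bits - 1
  stopifnot(adc_counts >= 0, adc_counts <= full, vref > 0, divider_r > 0)
  if (adc_counts == full)
    stop("ADC at full scale: open circuit, resistance unbounded")
  v <- adc_counts * vref / full
  divider_r * v / (vref - v)
}

#' Fall detector configuration
#'
#' Thresholds of the three-stage rule (free fall, impact, orientation
#' change), co-designed with the `fall` scenario of [gen_accel()] so the
#' labeled scenarios are separable.
#'
#' @param freefall_g Magnitude below which the trace counts as free
#'   fall, g.
#' @param impact_g Magnitude above which a sample counts as impact, g.
#' @param freefall_min_s Minimum free-fall duration, seconds.
#' @param impact_window_s How long after free fall the impact may
#'   arrive, seconds.
#' @param dwell_s Required duration of sustained horizontal orientation
#'   after the impact, seconds.
#' @param settle_s Dead time after the impact before orientation is
#'   judged, seconds.
#' @return An object of class `fall_config`.
#' @export
fall_config <- function(freefall_g = 0.4, impact_g = 2.5,
                        freefall_min_s = 0.06, impact_window_s = 0.5,
                        dwell_s = 1.0, settle_s = 0.2) {
  stopifnot(freefall_g > 0, impact_g > freefall_g, freefall_min_s > 0,
            impact_window_s > 0, dwell_s > 0, settle_s >= 0)
  structure(list(freefall_g = freefall_g, impact_g = impact_g,
                 freefall_min_s = freefall_min_s,
                 impact_window_s = impact_window_s,
                 dwell_s = dwell_s, settle_s = settle_s),
            class = "fall_config")
}

#' Detect falls in a tri-axial accelerometer trace
#'
#' A fall is an uncontrolled transition from vertical to horizontal: a
#' run of acceleration magnitude below the free-fall threshold lasting
#' at least `freefall_min_s`, followed within `impact_window_s` by a
#' sample above the impact threshold, followed by sustained horizontal
#' orientation (|x| or |y| dominating |z|) for `dwell_s`, with the
#' pre-fall posture vertical (|z| dominant). Slow deliberate lie-downs
#' produce no free-fall stage and therefore no event.
#'
#' @param trace An [accel_trace()] sampled at >= 20 Hz spanning >= 2 s.
#' @param cfg A [fall_config()].
#' @return A data frame of fall events with columns `index` (impact
#'   sample), `time_s`, `freefall_duration_s`, `impact_g`; zero rows if
#'   no fall is found.
#' @export
detect_fall <- function(trace, cfg = fall_config()) {
  stopifnot(inherits(trace, "accel_trace"), inherits(cfg, "fall_config"))
  fs <- trace$fs
  n <- length(trace$x)
  if (fs < 20) stop("accelerometer sampling rate must be >= 20 Hz")
  if (n < 2 * fs) stop("trace must span at least 2 s")
  mag <- sqrt(trace$x^2 + trace$y^2 + trace$z^2)
  horiz <- pmax(abs(trace$x), abs(trace$y)) > abs(trace$z)
  ff_min <- max(1L, round(cfg$freefall_min_s * fs))
  dwell_n <- round(cfg$dwell_s * fs)
  events <- list()
  below <- mag < cfg$freefall_g
  i <- 1L
  while (i <= n) {
    if (!below[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && below[j + 1L]) j <- j + 1L
    if (j - i + 1L >= ff_min) {
      # pre-fall posture must be vertical (majority of the 0.5 s before)
      pre <- max(1L, i - round(0.5 * fs)):max(1L, i - 1L)
      if (i > 1L && mean(horiz[pre]) < 0.5) {
        imp_end <- min(n, j + round(cfg$impact_window_s * fs))
        imp <- which(mag[(j + 1L):imp_end] > cfg$impact_g)
        if (length(imp) > 0L) {
          k <- j + imp[1L]
          d0 <- min(n, k + round(cfg$settle_s * fs))
          d1 <- min(n, d0 + dwell_n)
          if (d1 - d0 + 1L >= dwell_n && mean(horiz[d0:d1]) > 0.9) {
            events[[length(events) + 1L]] <- data.frame(
              index = k, time_s = (k - 1) / fs,
              freefall_duration_s = (j - i + 1L) / fs,
              impact_g = mag[k])
            i <- d1 + 1L
            next
          }
        }
      }
    }
    i <- j + 1L
  }
  if (length(events) == 0L)
    data.frame(index = integer(), time_s = numeric(),
               freefall_duration_s = numeric(), impact_g = numeric())
  else do.call(rbind, events)
}

#' One patient's measurement snapshot
#'
#' Union of the fields the fixed station (SpO2, respiration, GSR) and
#' the wearable node (temperature, heart rate, fall, location) report.
#' Fields not measured by the originating device are left `NULL` and
#' omitted from serializations.
#'
#' @param patient_id Integer patient identifier.
#' @param timestamp Measurement time, `POSIXct` or seconds since epoch.
#' @param temperature_c,hr_bpm,spo2_pct,respiration_bpm,gsr_ohms Optional
#'   measurements in degC, bpm, percent, breaths/min, ohms.
#' @param fall Logical fall flag (optional).
#' @param location Integer region / nearest-anchor id (optional).
#' @return An object of class `vitals_record`.
#' @export
vitals_record <- function(patient_id, timestamp = Sys.time(),
                          temperature_c = NULL, hr_bpm = NULL,
                          spo2_pct = NULL, respiration_bpm = NULL,
                          gsr_ohms = NULL, fall = NULL, location = NULL) {
  if (!is.null(spo2_pct) && (spo2_pct < 0 || spo2_pct > 100))
    stop("spo2_pct must lie in [0, 100]")
  if (inherits(timestamp, "POSIXct"))
    timestamp <- as.numeric(timestamp)
  # millisecond resolution: keeps the JSON timestamp round trip exact
  timestamp <- round(as.numeric(timestamp) * 1000) / 1000
  rec <- list(patient_id = as.integer(patient_id),
              timestamp = timestamp,
              temperature_c = temperature_c, hr_bpm = hr_bpm,
              spo2_pct = spo2_pct, respiration_bpm = respiration_bpm,
              gsr_ohms = gsr_ohms,
              fall = if (is.null(fall)) NULL else as.logical(fall),
              location = if (is.null(location)) NULL else
                as.integer(location))
  structure(rec[!vapply(rec, is.null, logical(1))], class = "vitals_record")
}
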