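#' Uniformly sampled waveform
#'
#' Container for a single-channel, uniformly sampled signal. Sample `i`
#' (1-based) corresponds to time `t0 + (i - 1) / fs` seconds.
#'
#' @param samples Numeric vector of sample values.
#' @param fs Sampling rate in Hz (> 0).
#' @param units Unit label for the sample values (e.g. "mV", "g").
#' @param t0 Start time of the first sample, seconds.
#' @return An object of class `waveform`: a list with elements `samples`,
#'   `fs`, `units`, `t0`.
#' @export
waveform <- function(samples, fs, units = "", t0 = 0) {
  stopifnot(is.numeric(samples), length(samples) >= 1L,
            is.numeric(fs), length(fs) == 1L, fs > 0,
            is.numeric(t0), length(t0) == 1L)
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs),
                 units = as.character(units), t0 = as.numeric(t0)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3f s)%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

#' Sample times of a waveform
#' @param x A `waveform`.
#' @return Numeric vector of sample times in seconds.
#' @export
wave_times <- function(x) {
  stopifnot(inherits(x, "waveform"))
  x$t0 + (seq_along(x$samples) - 1) / x$fs
}

#' Ground-truth annotation for a synthetic signal
#'
#' Holds the event sample indices (1-based, strictly increasing) and the
#' named scalar parameters a synthetic generator used, so estimators can
#' be scored against the truth.
#'
#' @param event_indices Integer vector of event sample indices (may be
#'   empty), strictly increasing.
#' @param scalar_params Named list of true generating parameters.
#' @param n_samples Length of the waveform the indices refer to, used to
#'   validate that all events fall inside the signal.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(event_indices = integer(), scalar_params = list(),
                         n_samples = NULL) {
  event_indices <- as.integer(event_indices)
  if (length(event_indices) > 1L && any(diff(event_indices) <= 0L))
    stop("event_indices must be strictly increasing")
  if (!is.null(n_samples) && length(event_indices) > 0L &&
      (min(event_indices) < 1L || max(event_indices) > n_samples))
    stop("event_indices must lie inside the waveform")
  structure(list(event_indices = event_indices,
                 scalar_params = scalar_params),
            class = "ground_truth")
}

#' Write a waveform as CSV with a JSON sidecar
#'
#' The CSV has columns `time_s,value`; the sidecar (same path with
#' `.json` appended) records `fs`, `units`, `t0` and any ground truth so
#' a reader can reconstruct the waveform and its annotations.
#'
#' @param x A `waveform`.
#' @param path Output CSV path.
#' @param truth Optional `ground_truth` to embed in the sidecar.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(x, path, truth = NULL) {
  stopifnot(inherits(x, "waveform"))
  df <- data.frame(time_s = wave_times(x), value = x$samples)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(fs = x$fs, units = x$units, t0 = x$t0)
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "ground_truth"))
    meta$ground_truth <- list(event_indices = truth$event_indices,
                              scalar_params = truth$scalar_params)
  }
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a waveform written by [write_waveform_csv()]
#'
#' @param path CSV path; the `.json` sidecar must sit next to it.
#' @return A list with `waveform` and (possibly `NULL`) `truth`.
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  wf <- waveform(df$value, fs = meta$fs, units = meta$units %||% "",
                 t0 = meta$t0 %||% 0)
  truth <- NULL
  if (!is.null(meta$ground_truth))
    truth <- ground_truth(meta$ground_truth$event_indices %||% integer(),
                          as.list(meta$ground_truth$scalar_params),
                          n_samples = length(wf$samples))
  list(waveform = wf, truth = truth)
}

#' Tri-axial accelerometer trace
#'
#' @param x,y,z Numeric vectors of equal length, acceleration in g.
#' @param fs Sampling rate in Hz.
#' @param scenario_label Optional label of the generating scenario
#'   (`"stand"`, `"walk"`, `"lie"`, `"fall"`), `NA` for real data.
#' @return An object of class `accel_trace`.
#' @export
accel_trace <- function(x, y, z, fs, scenario_label = NA_character_) {
  stopifnot(length(x) == length(y), length(y) == length(z),
            is.numeric(fs), fs > 0)
  structure(list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                 fs = as.numeric(fs),
                 scenario_label = as.character(scenario_label)),
            class = "accel_trace")
}

#' Write an accelerometer trace as 4-column CSV
#' @param trace An `accel_trace`.
#' @param path Output CSV path (columns `time_s,x_g,y_g,z_g`).
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(trace, path) {
  stopifnot(inherits(trace, "accel_trace"))
  t <- (seq_along(trace$x) - 1) / trace$fs
  utils::write.csv(data.frame(time_s = t, x_g = trace$x, y_g = trace$y,
                              z_g = trace$z), path, row.names = FALSE)
  invisible(path)
}

#' Dual-channel (red / infrared) photoplethysmogram
#'
#' @param red,ir `waveform`s sharing sampling rate and length.
#' @return An object of class `dual_ppg`.
#' @export
dual_ppg <- function(red, ir) {
  stopifnot(inherits(red, "waveform"), inherits(ir, "waveform"),
            red$fs == ir$fs, length(red$samples) == length(ir$samples))
  structure(list(red = red, ir = ir), class = "dual_ppg")
}
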