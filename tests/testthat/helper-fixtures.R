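# Shared fixtures and independent oracles used across the suite.

# Exhaustive single-pass scan of the thresholded absolute first
# derivative with the refractory skip rule; the independent reference
# the window-based detector must match on single-buffer inputs.
oracle_qrs_scan <- function(s, frac, refractory) {
  d <- abs(diff(s))
  if (length(d) == 0L || max(d) == 0) return(integer())
  thr <- frac * max(d)
  marks <- integer()
  i <- 1L
  while (i <= length(d)) {
    if (d[i] > thr) {
      marks <- c(marks, i)
      i <- i + 1L + refractory
    } else i <- i + 1L
  }
  marks
}

# random packet of a random type, with extreme field values mixed in
random_packet <- function() {
  type <- sample(c("fixed", "cont", "ecg"), 1)
  rint <- function() {
    if (runif(1) < 0.15) sample(c(-2147483647L, 2147483647L, 0L), 1)
    else sample.int(2^31 - 1, 1) * sample(c(-1L, 1L), 1)
  }
  if (type == "fixed") {
    fixed_station_packet(rint(), rint(),
                         blood_oxygen = runif(1, 0, 100),
                         respiration_rate = sample(0:32767, 1),
                         galvanic_resistance = runif(1, 0, 1e7))
  } else if (type == "cont") {
    continuous_packet(rint(), rint(),
                      temperature_c = runif(1, -10, 60),
                      heart_rate = runif(1, 20, 250),
                      fall = sample(0:1, 1), location = sample(1:100, 1))
  } else {
    ecg_packet(rint(), rint(), samples = rnorm(80))
  }
}

# diamond topology: remote -> {two equal relays} -> sink, with the
# direct remote-sink link out of range
diamond_network <- function() {
  wsn_network(data.frame(id = 1:4,
                         role = c("remote", "cluster", "cluster", "sink"),
                         x = c(0, 50, 50, 100), y = c(0, 20, -20, 0)))
}

diamond_cfg <- function() channel_config(sensitivity_dbm =
                                           range_to_sensitivity(70))
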