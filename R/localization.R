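# Range-free centroid indoor localization: a remote node is placed at
# the (optionally RSSI-weighted) mean of the anchor nodes that hear it.

#' Estimate a node position from anchor observations
#'
#' Plain mode is the classic range-free centroid: the arithmetic mean of
#' the positions of the anchors in range, independent of the RSSI
#' values. Weighted mode weights each anchor by its linearized received
#' power `10^(rssi/10)`.
#'
#' @param obs Data frame with columns `anchor_id`, `x`, `y` and (for
#'   weighted mode) `rssi_dbm`; one row per anchor that hears the node.
#' @param mode `"plain"` or `"weighted"`.
#' @param truth Optional true position `c(x, y)` for error computation.
#' @return An object of class `localization_estimate`: list with
#'   `position` (named x/y), `n_anchors`, `mode` and `error_m`
#'   (Euclidean distance to `truth`, `NA` if unknown).
#' @examples
#' obs <- data.frame(anchor_id = 1:4, x = c(0, 2, 0, 2), y = c(0, 0, 2, 2))
#' estimate_position(obs)$position  # (1, 1)
#' @export
estimate_position <- function(obs, mode = c("plain", "weighted"),
                              truth = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(obs), all(c("x", "y") %in% names(obs)))
  if (nrow(obs) == 0L) stop("no anchors in range: position unobservable")
  w <- if (mode == "weighted") {
    stopifnot("rssi_dbm" %in% names(obs))
    10^(obs$rssi_dbm / 10)
  } else rep(1, nrow(obs))
  pos <- c(x = sum(w * obs$x) / sum(w), y = sum(w * obs$y) / sum(w))
  err <- if (is.null(truth)) NA_real_ else
    sqrt((pos[["x"]] - truth[1])^2 + (pos[["y"]] - truth[2])^2)
  structure(list(position = pos, n_anchors = nrow(obs), mode = mode,
                 error_m = err),
            class = "localization_estimate")
}

#' Rectangular anchor grid
#'
#' `nx * ny` anchors at the cell centers of a uniform grid over a
#' `w x h` meter area -- the deployment fixture used for accuracy
#' evaluation (default: 12 anchors over the 27 m x 17 m pilot floor).
#'
#' @param nx,ny Grid dimensions.
#' @param area Area size `c(w, h)` in meters.
#' @return Data frame `anchor_id, x, y`.
#' @export
anchor_grid <- function(nx = 4, ny = 3, area = c(27, 17)) {
  stopifnot(nx >= 1, ny >= 1, all(area > 0))
  g <- expand.grid(x = (seq_len(nx) - 0.5) * area[1] / nx,
                   y = (seq_len(ny) - 0.5) * area[2] / ny)
  data.frame(anchor_id = seq_len(nrow(g)), x = g$x, y = g$y)
}

#' Evaluate centroid localization accuracy over an area
#'
#' Samples node positions uniformly in the area, determines which
#' anchors hear each one through the path-loss model and the receiver
#' sensitivity, estimates every position with [estimate_position()], and
#' summarizes the Euclidean error over the covered positions.
#'
#' @param anchors Data frame `anchor_id, x, y` (>= 3 anchors).
#' @param area Area `c(w, h)`, meters.
#' @param n_positions Number of sampled positions (>= 100).
#' @param cfg A [channel_config()]; `sensitivity_dbm` sets the radio
#'   range (see [range_to_sensitivity()]).
#' @param mode `"plain"` or `"weighted"` centroid.
#' @param seed Integer seed.
#' @return List with `mean_error_m`, `max_error_m`, `coverage`
#'   (fraction of positions hearing >= 1 anchor), `n_positions`,
#'   `n_covered`, and the per-position `errors`.
#' @export
evaluate_localization <- function(anchors, area = c(27, 17),
                                  n_positions = 1000,
                                  cfg = channel_config(),
                                  mode = c("plain", "weighted"),
                                  seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(nrow(anchors) >= 3, n_positions >= 100)
  with_seed(seed, {
    px <- runif(n_positions, 0, area[1])
    py <- runif(n_positions, 0, area[2])
    errors <- rep(NA_real_, n_positions)
    for (i in seq_len(n_positions)) {
      d <- sqrt((anchors$x - px[i])^2 + (anchors$y - py[i])^2)
      rssi <- rssi_model(pmax(d, 1e-6), cfg)
      inr <- rssi >= cfg$sensitivity_dbm
      if (!any(inr)) next
      obs <- data.frame(anchor_id = anchors$anchor_id[inr],
                        x = anchors$x[inr], y = anchors$y[inr],
                        rssi_dbm = rssi[inr])
      errors[i] <- estimate_position(obs, mode,
                                     truth = c(px[i], py[i]))$error_m
    }
    covered <- !is.na(errors)
    if (!any(covered)) stop("zero coverage: no position heard any anchor")
    list(mean_error_m = mean(errors[covered]),
         max_error_m = max(errors[covered]),
         coverage = mean(covered),
         n_positions = n_positions,
         n_covered = sum(covered),
         errors = errors)
  })
}

#' Region id of the nearest anchor
#'
#' The integer location field carried in continuous-sampling packets is
#' the id of the closest anchor (a room/region proxy); continuous
#' coordinates live only in simulator output.
#'
#' @param position `c(x, y)` meters.
#' @param anchors Data frame `anchor_id, x, y`.
#' @return The `anchor_id` of the nearest anchor.
#' @export
nearest_region <- function(position, anchors) {
  d <- (anchors$x - position[1])^2 + (anchors$y - position[2])^2
  anchors$anchor_id[which.min(d)]
}
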