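# Discrete-event simulator of the hierarchical body-sensor network:
# four node roles (remote / cluster / gateway / sink), link weights from
# RSSI, hop count and remaining node lifetime (TTL), redundant routing
# tables with fallback, slotted CSMA/CA-style contention, node failure
# and rejoin, and exact traffic accounting.

#' Radio channel configuration
#'
#' Log-distance path-loss channel plus the abstract medium-access
#' parameters of the simulator.
#'
#' @param path_loss_exp Path-loss exponent (2 = free space).
#' @param ref_loss_db Loss at the 1 m reference distance, dB.
#' @param tx_dbm Transmit power, dBm.
#' @param sensitivity_dbm Receiver sensitivity, dBm; links below it do
#'   not exist.
#' @param noise_sd_db Shadowing noise sd, dB (0 = deterministic).
#' @param slot_s CSMA slot length, seconds.
#' @param backoff_slots Uniform backoff window, slots.
#' @param loss_floor Per-hop independent packet-loss probability.
#' @param retry_limit Collision retries before the packet is dropped.
#' @return An object of class `channel_config`.
#' @export
channel_config <- function(path_loss_exp = 2.0, ref_loss_db = 40,
                           tx_dbm = 0, sensitivity_dbm = -90,
                           noise_sd_db = 0, slot_s = 0.01,
                           backoff_slots = 8L, loss_floor = 0,
                           retry_limit = 3L) {
  stopifnot(sensitivity_dbm < tx_dbm, loss_floor >= 0, loss_floor <= 1,
            path_loss_exp > 0, slot_s > 0, backoff_slots >= 1,
            retry_limit >= 0)
  structure(list(path_loss_exp = path_loss_exp, ref_loss_db = ref_loss_db,
                 tx_dbm = tx_dbm, sensitivity_dbm = sensitivity_dbm,
                 noise_sd_db = noise_sd_db, slot_s = slot_s,
                 backoff_slots = as.integer(backoff_slots),
                 loss_floor = loss_floor,
                 retry_limit = as.integer(retry_limit)),
            class = "channel_config")
}

#' Received signal strength at a distance
#'
#' Log-distance path loss:
#' `rssi = tx - (L0 + 10 n log10(d)) + N(0, noise_sd)`.
#'
#' @param distance_m Distance(s) in meters, > 0.
#' @param cfg A [channel_config()].
#' @param seed Optional integer seed for the shadowing draw.
#' @return RSSI in dBm (vectorized over `distance_m`).
#' @export
rssi_model <- function(distance_m, cfg = channel_config(), seed = NULL) {
  if (any(distance_m <= 0)) stop("distance must be > 0")
  with_seed(seed, {
    r <- cfg$tx_dbm -
      (cfg$ref_loss_db + 10 * cfg$path_loss_exp * log10(distance_m))
    if (cfg$noise_sd_db > 0)
      r <- r + rnorm(length(distance_m), sd = cfg$noise_sd_db)
    r
  })
}

#' Receiver sensitivity giving a wanted deterministic radio range
#'
#' Convenience inverse of [rssi_model()]: the RSSI at `range_m` under a
#' noise-free channel, so that setting `sensitivity_dbm` to the returned
#' value makes links reach exactly `range_m`.
#'
#' @param range_m Wanted radio range, m.
#' @param cfg A [channel_config()] (its noise is ignored).
#' @return Sensitivity in dBm.
#' @export
range_to_sensitivity <- function(range_m, cfg = channel_config()) {
  cfg$tx_dbm - (cfg$ref_loss_db +
                  10 * cfg$path_loss_exp * log10(range_m))
}

#' Routing link weight from RSSI, hop count and node lifetime
#'
#' The routing metric combines the three stated ingredients as a linear
#' weighted sum of terms normalized to \[0, 1\] over declared ranges;
#' higher is better: strong links, few hops and long remaining lifetime
#' are preferred.
#'
#' @param rssi_dbm Link RSSI, dBm.
#' @param hops Route length via this link, hops to the sink (>= 1).
#' @param ttl Remaining lifetime of the next-hop node, arbitrary
#'   lifetime units.
#' @param weights Named numeric: `rssi`, `hops`, `ttl` contributions.
#' @param ranges Normalization ranges: list with `rssi` (c(min, max)
#'   dBm), `hops_max`, `ttl_max`.
#' @return Scalar weight; strictly increasing in RSSI and TTL, strictly
#'   decreasing in hops (within the declared ranges).
#' @export
link_weight <- function(rssi_dbm, hops, ttl,
                        weights = c(rssi = 0.5, hops = 0.3, ttl = 0.2),
                        ranges = list(rssi = c(-100, 0), hops_max = 16,
                                      ttl_max = 100)) {
  if (any(hops < 1)) stop("hops must be >= 1")
  if (any(ttl < 0)) stop("ttl must be >= 0")
  clamp01 <- function(x) pmin(1, pmax(0, x))
  nr <- clamp01((rssi_dbm - ranges$rssi[1]) / diff(ranges$rssi))
  nh <- clamp01((hops - 1) / (ranges$hops_max - 1))
  nt <- clamp01(ttl / ranges$ttl_max)
  weights[["rssi"]] * nr - weights[["hops"]] * nh + weights[["ttl"]] * nt
}

#' Build a sensor network from a node table
#'
#' @param nodes Data frame with columns `id` (unique integers), `role`
#'   (`"remote"`, `"cluster"`, `"gateway"`, `"sink"` -- exactly one
#'   sink), `x`, `y` (meters) and optionally `ttl` (default 100) and
#'   `alive` (default `TRUE`).
#' @return An object of class `wsn_network`.
#' @export
wsn_network <- function(nodes) {
  stopifnot(is.data.frame(nodes),
            all(c("id", "role", "x", "y") %in% names(nodes)))
  if (anyDuplicated(nodes$id)) stop("node ids must be unique")
  if (!all(nodes$role %in% c("remote", "cluster", "gateway", "sink")))
    stop("unknown role")
  if (sum(nodes$role == "sink") != 1L)
    stop("network must contain exactly one sink")
  if (is.null(nodes$ttl)) nodes$ttl <- 100
  if (is.null(nodes$alive)) nodes$alive <- TRUE
  structure(list(nodes = nodes), class = "wsn_network")
}

# deterministic pairwise RSSI used for topology decisions
.pairwise_rssi <- function(nodes, cfg) {
  d <- as.matrix(stats::dist(nodes[, c("x", "y")]))
  diag(d) <- NA
  r <- cfg$tx_dbm - (cfg$ref_loss_db +
                       10 * cfg$path_loss_exp * log10(d))
  dimnames(r) <- list(nodes$id, nodes$id)
  r
}

#' Build redundant routing tables toward the sink
#'
#' Hop counts are breadth-first distances from the sink over the
#' in-range graph of alive nodes; every in-range neighbor strictly
#' closer to the sink becomes a routing entry (remote nodes never relay),
#' ordered best-weight-first by [link_weight()]. Nodes with no path are
#' flagged unreachable, not fatal.
#'
#' @param net A [wsn_network()].
#' @param cfg A [channel_config()] (deterministic RSSI is used for
#'   topology).
#' @param weights,ranges Passed to [link_weight()].
#' @return An object of class `routing_tables`: list with `routes`
#'   (named list of data frames `next_hop, weight, rssi_dbm, hops`),
#'   `hops` (named hop counts, `Inf` if unreachable) and `unreachable`
#'   (ids).
#' @export
build_routes <- function(net, cfg = channel_config(),
                         weights = c(rssi = 0.5, hops = 0.3, ttl = 0.2),
                         ranges = list(rssi = c(-100, 0), hops_max = 16,
                                       ttl_max = 100)) {
  stopifnot(inherits(net, "wsn_network"))
  nodes <- net$nodes
  rssi <- .pairwise_rssi(nodes, cfg)
  alive <- nodes$alive
  inrange <- !is.na(rssi) & rssi >= cfg$sensitivity_dbm &
    outer(alive, alive, `&`)
  # remote nodes originate traffic only: no one routes through them
  can_relay <- nodes$role != "remote"
  n <- nrow(nodes)
  hops <- rep(Inf, n)
  sink_i <- which(nodes$role == "sink")
  hops[sink_i] <- 0
  frontier <- sink_i
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (i in frontier) {
      nb <- which(inrange[, i] & is.infinite(hops))
      hops[nb] <- hops[i] + 1
      nxt <- c(nxt, nb[can_relay[nb]])   # remotes are leaves, never expanded
    }
    frontier <- unique(nxt)
  }
  routes <- stats::setNames(vector("list", n), nodes$id)
  for (i in seq_len(n)) {
    if (i == sink_i || is.infinite(hops[i])) {
      routes[[i]] <- data.frame(next_hop = integer(), weight = numeric(),
                                rssi_dbm = numeric(), hops = numeric())
      next
    }
    nb <- which(inrange[i, ] & can_relay & hops < hops[i])
    if (length(nb) == 0L) {
      routes[[i]] <- data.frame(next_hop = integer(), weight = numeric(),
                                rssi_dbm = numeric(), hops = numeric())
      next
    }
    w <- link_weight(rssi[i, nb], hops[nb] + 1, nodes$ttl[nb],
                     weights = weights, ranges = ranges)
    ord <- order(w, decreasing = TRUE)
    routes[[i]] <- data.frame(next_hop = nodes$id[nb][ord],
                              weight = w[ord],
                              rssi_dbm = rssi[i, nb][ord],
                              hops = hops[nb][ord] + 1)
  }
  unreachable <- nodes$id[is.infinite(hops) & nodes$role != "sink"]
  structure(list(routes = routes,
                 hops = stats::setNames(hops, nodes$id),
                 unreachable = unreachable),
            class = "routing_tables")
}

#' Run the network simulation
#'
#' Event-driven delivery of a traffic schedule. Each packet follows the
#' best alive routing entry hop by hop; per hop it contends for the
#' slotted shared medium (listen, uniform random backoff on a busy slot,
#' drop after `retry_limit` collisions), suffers the independent
#' per-hop `loss_floor`, and falls back to the next routing entry when
#' its next hop is dead. Scheduled node failures and rejoins are applied
#' in time order; a rejoining node triggers a route rebuild and adopts
#' the best-suited role (cluster if a remote node is in range, else
#' gateway).
#'
#' @param net A [wsn_network()].
#' @param traffic Data frame with `time` (s) and `src` (node id); one
#'   row per generated packet.
#' @param cfg A [channel_config()].
#' @param events Optional data frame `time, node_id, action` with action
#'   `"fail"` or `"rejoin"`.
#' @param seed Integer seed; the run is bit-for-bit reproducible.
#' @param weights Routing-metric weights, see [link_weight()].
#' @param drop_schedule Optional integer vector of packet ids (row
#'   numbers of `traffic`) deliberately dropped at their first hop --
#'   the loss-injection hook used to validate the accounting.
#' @return An object of class `sim_result`: `generated`, `delivered`,
#'   `lost`, `loss_pct` (= 100 * lost / generated) and a per-packet
#'   `trace` data frame (`packet_id, src, t_gen, delivered, reason,
#'   hops, t_done`).
#' @export
run_simulation <- function(net, traffic, cfg = channel_config(),
                           events = NULL, seed = NULL,
                           weights = c(rssi = 0.5, hops = 0.3, ttl = 0.2),
                           drop_schedule = NULL) {
  stopifnot(inherits(net, "wsn_network"), is.data.frame(traffic))
  if (nrow(traffic) == 0L) stop("empty traffic schedule")
  stopifnot(all(c("time", "src") %in% names(traffic)))
  nodes <- net$nodes
  id2i <- stats::setNames(seq_len(nrow(nodes)), nodes$id)
  sink_id <- nodes$id[nodes$role == "sink"]
  traffic <- traffic[order(traffic$time), , drop = FALSE]
  if (!is.null(events)) {
    stopifnot(all(c("time", "node_id", "action") %in% names(events)))
    events <- events[order(events$time), , drop = FALSE]
  }
  with_seed(seed, {
    rt <- build_routes(wsn_network(nodes), cfg, weights)
    ev_i <- 1L
    busy <- new.env(parent = emptyenv())   # slot index -> TRUE
    m <- nrow(traffic)
    status <- logical(m); reason <- character(m)
    hops_used <- integer(m); t_done <- numeric(m)
    for (p in seq_len(m)) {
      t <- traffic$time[p]
      # apply due failure / rejoin events, rebuilding routes on change
      while (!is.null(events) && ev_i <= nrow(events) &&
             events$time[ev_i] <= t) {
        ni <- id2i[[as.character(events$node_id[ev_i])]]
        if (events$action[ev_i] == "fail") {
          nodes$alive[ni] <- FALSE
        } else {
          nodes$alive[ni] <- TRUE
          nodes$role[ni] <- .elect_role(nodes, ni, cfg)
          rt <- build_routes(wsn_network(nodes), cfg, weights)
        }
        ev_i <- ev_i + 1L
      }
      if (!is.null(drop_schedule) && p %in% drop_schedule) {
        reason[p] <- "injected"; t_done[p] <- t
        next
      }
      cur <- traffic$src[p]
      nh <- 0L; ok <- NA
      while (TRUE) {
        if (cur == sink_id) { ok <- TRUE; break }
        entries <- rt$routes[[as.character(cur)]]
        entries <- entries[nodes$alive[id2i[as.character(entries$next_hop)]], ,
                           drop = FALSE]
        if (nrow(entries) == 0L) { ok <- FALSE; reason[p] <- "no_route"; break }
        # CSMA/CA: listen; on a busy slot back off uniformly, retrying
        tries <- 0L
        repeat {
          slot <- as.character(floor(t / cfg$slot_s))
          if (!exists(slot, envir = busy, inherits = FALSE)) {
            assign(slot, TRUE, envir = busy)
            break
          }
          tries <- tries + 1L
          if (tries > cfg$retry_limit) break
          t <- t + sample.int(cfg$backoff_slots, 1L) * cfg$slot_s
        }
        if (tries > cfg$retry_limit) { ok <- FALSE; reason[p] <- "collision"; break }
        if (cfg$loss_floor > 0 && runif(1) < cfg$loss_floor) {
          ok <- FALSE; reason[p] <- "channel"; break
        }
        nodes$ttl[id2i[[as.character(cur)]]] <-
          max(0, nodes$ttl[id2i[[as.character(cur)]]] - 1)   # battery proxy
        cur <- entries$next_hop[1L]
        nh <- nh + 1L
        t <- t + cfg$slot_s
      }
      status[p] <- isTRUE(ok)
      if (status[p]) reason[p] <- "delivered"
      hops_used[p] <- nh; t_done[p] <- t
    }
    generated <- m
    delivered <- sum(status)
    lost <- generated - delivered
    structure(list(generated = generated, delivered = delivered,
                   lost = lost, loss_pct = 100 * lost / generated,
                   trace = data.frame(packet_id = seq_len(m),
                                      src = traffic$src,
                                      t_gen = traffic$time,
                                      delivered = status, reason = reason,
                                      hops = hops_used, t_done = t_done)),
              class = "sim_result")
  })
}

# role election for a rejoining node: cluster if any remote is in radio
# range, otherwise gateway
.elect_role <- function(nodes, ni, cfg) {
  if (nodes$role[ni] %in% c("sink", "remote")) return(nodes$role[ni])
  d <- sqrt((nodes$x - nodes$x[ni])^2 + (nodes$y - nodes$y[ni])^2)
  d[ni] <- NA
  rssi <- ifelse(is.na(d) | d == 0, cfg$tx_dbm,
                 cfg$tx_dbm - (cfg$ref_loss_db +
                                 10 * cfg$path_loss_exp * log10(pmax(d, 1e-9))))
  inr <- !is.na(d) & rssi >= cfg$sensitivity_dbm & nodes$alive
  if (any(inr & nodes$role == "remote")) "cluster" else "gateway"
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> generated %d, delivered %d, lost %d (%.2f%%)\n",
              x$generated, x$delivered, x$lost, x$loss_pct))
  invisible(x)
}
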