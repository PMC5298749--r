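test_that("path-loss RSSI follows the log-distance model", {
  cfg <- channel_config()
  expect_equal(rssi_model(1, cfg), cfg$tx_dbm - cfg$ref_loss_db)
  # doubling distance with exponent 2 costs 10 * 2 * log10(2) dB
  drop <- rssi_model(10, cfg) - rssi_model(20, cfg)
  expect_equal(drop, 20 * log10(2), tolerance = 1e-9)
  expect_error(rssi_model(0, cfg), "distance")
})

test_that("link weight is monotone in each routing ingredient", {
  # fewer hops win, all else equal
  expect_gt(link_weight(-70, 1, 50), link_weight(-70, 3, 50))
  # stronger RSSI wins
  expect_gt(link_weight(-60, 2, 50), link_weight(-90, 2, 50))
  # longer remaining lifetime wins
  expect_gt(link_weight(-70, 2, 100), link_weight(-70, 2, 0))
  expect_error(link_weight(-70, 0, 50), "hops")
})

test_that("routing tables hold every closer neighbor, best first", {
  # chain: remote only hears the cluster; cluster only the sink
  chain <- wsn_network(data.frame(
    id = 1:3, role = c("remote", "cluster", "sink"),
    x = c(0, 50, 100), y = 0))
  cfg <- channel_config(sensitivity_dbm = range_to_sensitivity(60))
  rt <- build_routes(chain, cfg)
  expect_identical(rt$routes[["1"]]$next_hop, 2L)
  expect_identical(rt$routes[["2"]]$next_hop, 3L)

  # diamond: two equal-hop relays -> the source stores both entries
  rtd <- build_routes(diamond_network(), diamond_cfg())
  expect_setequal(rtd$routes[["1"]]$next_hop, c(2L, 3L))
  expect_true(all(diff(rtd$routes[["1"]]$weight) <= 0))  # sorted best-first
})

test_that("an isolated node is flagged unreachable, not fatal", {
  net <- wsn_network(data.frame(
    id = 1:3, role = c("remote", "cluster", "sink"),
    x = c(0, 5, 2000), y = 0))
  rt <- build_routes(net, channel_config(sensitivity_dbm =
                                           range_to_sensitivity(50)))
  expect_true(all(c(1, 2) %in% rt$unreachable))
})

test_that("remote nodes never appear as relays", {
  net <- wsn_network(data.frame(
    id = 1:4, role = c("remote", "remote", "cluster", "sink"),
    x = c(0, 25, 50, 100), y = 0))
  rt <- build_routes(net, channel_config(sensitivity_dbm =
                                           range_to_sensitivity(60)))
  hops_via <- unlist(lapply(rt$routes, function(r) r$next_hop))
  expect_false(any(hops_via %in% c(1L, 2L)))
})

test_that("a lossless single link delivers everything", {
  net <- wsn_network(data.frame(id = 1:2, role = c("remote", "sink"),
                                x = c(0, 5), y = 0))
  res <- run_simulation(net, data.frame(time = 0:99, src = 1L), seed = 1)
  expect_identical(res$delivered, 100L)
  expect_equal(res$loss_pct, 0)
})

test_that("packet conservation holds in every run", {
  cfg <- channel_config(loss_floor = 0.05,
                        sensitivity_dbm = range_to_sensitivity(70))
  for (seed in 1:5) {
    res <- run_simulation(diamond_network(),
                          data.frame(time = seq(0, 49.5, by = 0.5),
                                     src = 1L), cfg, seed = seed)
    expect_identical(res$generated, res$delivered + res$lost)
    expect_equal(res$loss_pct, 100 * res$lost / res$generated)
  }
})

test_that("fixed seeds reproduce the simulation bit-for-bit", {
  cfg <- channel_config(loss_floor = 0.1,
                        sensitivity_dbm = range_to_sensitivity(70))
  tr <- data.frame(time = seq(0, 99, by = 0.2), src = 1L)
  expect_identical(run_simulation(diamond_network(), tr, cfg, seed = 11),
                   run_simulation(diamond_network(), tr, cfg, seed = 11))
})

test_that("redundant entries keep delivery intact through a relay kill", {
  tr <- data.frame(time = 0:99, src = 1L)
  base <- run_simulation(diamond_network(), tr, diamond_cfg(), seed = 5)
  for (relay in c(2L, 3L)) {
    ev <- data.frame(time = 50, node_id = relay, action = "fail")
    res <- run_simulation(diamond_network(), tr, diamond_cfg(),
                          events = ev, seed = 5)
    expect_identical(res$delivered, res$generated)
    expect_identical(res$delivered, base$delivered)
  }
})

test_that("a dead relay without redundancy loses, a rejoin restores", {
  chain <- wsn_network(data.frame(
    id = 1:3, role = c("remote", "cluster", "sink"),
    x = c(0, 50, 100), y = 0))
  cfg <- channel_config(sensitivity_dbm = range_to_sensitivity(60))
  ev <- data.frame(time = c(30, 60), node_id = 2L,
                   action = c("fail", "rejoin"))
  res <- run_simulation(chain, data.frame(time = 0:99, src = 1L), cfg,
                        events = ev, seed = 1)
  lost_window <- res$trace$t_gen >= 30 & res$trace$t_gen < 60
  expect_true(all(!res$trace$delivered[lost_window]))
  expect_true(all(res$trace$delivered[!lost_window]))
  expect_identical(res$lost, sum(lost_window))
})

test_that("adding relays never hurts a lossless, contention-free run", {
  tr <- data.frame(time = 0:49, src = 1L)
  cfg <- channel_config(sensitivity_dbm = range_to_sensitivity(70))
  small <- run_simulation(diamond_network(), tr, cfg, seed = 2)
  bigger <- wsn_network(rbind(diamond_network()$nodes,
                              data.frame(id = 5:6, role = "gateway",
                                         x = c(30, 70), y = c(0, 0),
                                         ttl = 100, alive = TRUE)))
  big <- run_simulation(bigger, tr, cfg, seed = 2)
  expect_gte(big$delivered / big$generated,
             small$delivered / small$generated)
})

test_that("simultaneous senders contend and may collide out", {
  # many packets in the same instant from two remotes through one relay
  net <- wsn_network(data.frame(
    id = 1:4, role = c("remote", "remote", "cluster", "sink"),
    x = c(0, 0, 50, 100), y = c(1, -1, 0, 0)))
  cfg <- channel_config(sensitivity_dbm = range_to_sensitivity(60),
                        retry_limit = 1L, backoff_slots = 2L)
  tr <- data.frame(time = rep(0, 40), src = rep(c(1L, 2L), 20))
  res <- run_simulation(net, tr, cfg, seed = 3)
  expect_gt(res$lost, 0)
  expect_true(all(res$trace$reason[!res$trace$delivered] == "collision"))
})

test_that("the empty traffic schedule is rejected", {
  expect_error(run_simulation(diamond_network(),
                              data.frame(time = numeric(), src = integer())),
               "empty traffic")
})
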