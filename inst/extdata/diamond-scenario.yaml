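# Example network scenario: one remote node with two redundant relays.
# Usable with the `simulate-network` CLI command or loaded manually.
nodes:
  id: [1, 2, 3, 4]
  role: [remote, cluster, cluster, sink]
  x: [0, 50, 50, 100]
  "y": [0, 20, -20, 0]   # quoted: bare y is YAML-1.1 boolean
channel:
  sensitivity_dbm: -76.9
  loss_floor: 0.0
traffic:
  time: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9]
  src: [1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
events:
  time: [5]
  node_id: [2]
  action: [fail]
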