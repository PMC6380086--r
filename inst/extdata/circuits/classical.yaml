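name: classical
nodes:
- sense(cs)
- sense(us)
- motor(X)
sensors:
- sense(cs)
- sense(us)
effectors:
- motor(X)
connectors:
- kind: synapse
  endpoints:
  - sense(us)
  - motor(X)
- kind: synapse
  endpoints:
  - sense(cs)
  - motor(X)
- kind: modulation_up
  endpoints:
  - sense(us)
  - sense(cs)
  - motor(X)
- kind: choice
  endpoints:
  - sense(us)
  - sense(cs)
  - motor(X)
weights:
- p: sense(us)
  q: motor(X)
  w: 1
- p: sense(cs)
  q: motor(X)
  w: 0
rules: []
stm_capacity: 1
stm_initial: []
ltm_initial: []
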