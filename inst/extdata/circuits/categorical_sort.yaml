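name: categorical_sort
nodes:
- sense(study(item(N),color(C)))
- sense(assign(color(C),bin(B)))
- sense(sort(item(N)))
- scribe(item(N),color(C))
- binder(color(C),bin(B))
- sorter(item(N),C,B)
sensors:
- sense(study(item(N),color(C)))
- sense(assign(color(C),bin(B)))
- sense(sort(item(N)))
effectors: []
connectors:
- kind: synapse
  endpoints:
  - sense(study(item(N),color(C)))
  - scribe(item(N),color(C))
- kind: synapse
  endpoints:
  - sense(assign(color(C),bin(B)))
  - binder(color(C),bin(B))
- kind: synapse
  endpoints:
  - sense(sort(item(N)))
  - sorter(item(N),C,B)
weights:
- p: sense(study(item(N),color(C)))
  q: scribe(A,B)
  w: 1
- p: sense(assign(color(C),bin(B)))
  q: binder(A,B)
  w: 1
- p: sense(sort(item(N)))
  q: sorter(A,B,C)
  w: 1
rules:
- thread: scribe(item(N),color(C))
  clock: 1
  instr: receive(sense(A),P)
- thread: scribe(item(N),color(C))
  clock: 2
  instr: store(color(item(N),C))
- thread: binder(color(C),bin(B))
  clock: 1
  instr: receive(sense(A),P)
- thread: binder(color(C),bin(B))
  clock: 2
  instr: store(category(C,bin(B)))
- thread: sorter(item(N),C,B)
  clock: 1
  instr: receive(sense(A),P)
- thread: sorter(item(N),C,B)
  clock: 2
  instr: retrieve(color(item(N),C))
- thread: sorter(item(N),C,B)
  clock: 3
  instr: retrieve(category(C,bin(B)))
- thread: sorter(item(N),C,B)
  clock: 4
  instr: act(put(item(N),bin(B)))
stm_capacity: 1
stm_initial: []
ltm_initial: []
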