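name: win_stay_lose_shift
nodes:
- sense(go)
- wsls(last(A,B))
- pick
- press(left)
- press(right)
- reward(A)
- punish(A)
sensors:
- sense(go)
effectors:
- press(left)
- press(right)
connectors:
- kind: synapse
  endpoints:
  - sense(go)
  - wsls(last(A,B))
weights:
- p: sense(go)
  q: wsls(A)
  w: 1
- p: wsls(A)
  q: press(X)
  w: 1
- p: wsls(A)
  q: pick
  w: 1
- p: pick
  q: press(X)
  w: 1
rules:
- thread: wsls(last(A,B))
  clock: 1
  instr: receive(sense(go),G)
- thread: wsls(last(A,B))
  clock: 2
  instr: pull(last(A,B))
- thread: wsls(last(A,win))
  clock: 3
  instr: send(press(A),go(press(A)))
- thread: wsls(last(left,lose))
  clock: 3
  instr: send(press(right),go(press(right)))
- thread: wsls(last(right,lose))
  clock: 3
  instr: send(press(left),go(press(left)))
- thread: wsls(last(none,none))
  clock: 3
  instr: emit(fetch(wsls),pick)
- thread: pick
  clock: 1
  instr: receive(wsls(A),fetch(F))
- thread: pick
  clock: 2
  instr: choose(press(left),press(right))
- thread: press(left)
  clock: 1
  instr: receive(any(wsls(A),pick),P)
- thread: press(left)
  clock: 2
  instr: act(press(left))
- thread: press(right)
  clock: 1
  instr: receive(any(wsls(A),pick),P)
- thread: press(right)
  clock: 2
  instr: act(press(right))
- thread: reward(press(B))
  clock: 1
  instr: emit(excite(press(B)))
- thread: reward(press(B))
  clock: 2
  instr: push(last(B,win))
- thread: punish(press(B))
  clock: 1
  instr: emit(inhibit(press(B)))
- thread: punish(press(B))
  clock: 2
  instr: push(last(B,lose))
stm_capacity: 1
stm_initial:
- last(none,none)
ltm_initial: []
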