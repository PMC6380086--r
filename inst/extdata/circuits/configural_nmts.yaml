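name: configural_nmts
nodes:
- sense(left(L))
- sense(right(R))
- sense(sample(S))
- cfg(left(L),right(R),sample(S))
- explore(K)
- pick
- press(left)
- press(right)
- reward(A)
- punish(A)
- ltp(A,K)
- ltd(K)
sensors:
- sense(left(L))
- sense(right(R))
- sense(sample(S))
effectors:
- press(left)
- press(right)
connectors:
- kind: synapse
  endpoints:
  - sense(left(L))
  - cfg(left(L),right(R),sample(S))
- kind: synapse
  endpoints:
  - sense(right(R))
  - cfg(left(L),right(R),sample(S))
- kind: synapse
  endpoints:
  - sense(sample(S))
  - cfg(left(L),right(R),sample(S))
weights:
- p: sense(left(L))
  q: cfg(A,B,C)
  w: 1
- p: sense(right(R))
  q: cfg(A,B,C)
  w: 1
- p: sense(sample(S))
  q: cfg(A,B,C)
  w: 1
- p: explore(K)
  q: pick
  w: 1
- p: pick
  q: press(left)
  w: 1
- p: pick
  q: press(right)
  w: 1
- p: reward(A)
  q: ltp(B,K)
  w: 1
- p: reward(A)
  q: ltd(K)
  w: 1
- p: cfg(left([red]),right([green]),sample([red]))
  q: press(left)
  w: 0
- p: cfg(left([red]),right([green]),sample([red]))
  q: press(right)
  w: 0
- p: cfg(left([red]),right([green]),sample([red]))
  q: explore(cfg(left([red]),right([green]),sample([red])))
  w: 1
- p: cfg(left([red]),right([green]),sample([green]))
  q: press(left)
  w: 0
- p: cfg(left([red]),right([green]),sample([green]))
  q: press(right)
  w: 0
- p: cfg(left([red]),right([green]),sample([green]))
  q: explore(cfg(left([red]),right([green]),sample([green])))
  w: 1
- p: cfg(left([green]),right([red]),sample([red]))
  q: press(left)
  w: 0
- p: cfg(left([green]),right([red]),sample([red]))
  q: press(right)
  w: 0
- p: cfg(left([green]),right([red]),sample([red]))
  q: explore(cfg(left([green]),right([red]),sample([red])))
  w: 1
- p: cfg(left([green]),right([red]),sample([green]))
  q: press(left)
  w: 0
- p: cfg(left([green]),right([red]),sample([green]))
  q: press(right)
  w: 0
- p: cfg(left([green]),right([red]),sample([green]))
  q: explore(cfg(left([green]),right([red]),sample([green])))
  w: 1
rules:
- thread: cfg(left(L),right(R),sample(S))
  clock: 1
  instr: receive(sense(left(Z)),left(L))
- thread: cfg(left(L),right(R),sample(S))
  clock: 2
  instr: receive(sense(right(Z)),right(R))
- thread: cfg(left(L),right(R),sample(S))
  clock: 3
  instr: receive(sense(sample(Z)),sample(S))
- thread: cfg(left(L),right(R),sample(S))
  clock: 4
  instr: send(press(left),offer(left))
- thread: cfg(left(L),right(R),sample(S))
  clock: 5
  instr: send(press(right),offer(right))
- thread: cfg(left(L),right(R),sample(S))
  clock: 6
  instr: merge(active_key(cfg(left(L),right(R),sample(S))))
- thread: cfg(left(L),right(R),sample(S))
  clock: 7
  instr: send(explore(cfg(left(L),right(R),sample(S))),go(explore))
- thread: explore(K)
  clock: 1
  instr: receive(cfg(A,B,C),G)
- thread: explore(K)
  clock: 2
  instr: merge(learn_tok(K))
- thread: explore(K)
  clock: 3
  instr: emit(fetch(K),pick)
- thread: pick
  clock: 1
  instr: receive(explore(K),fetch(F))
- thread: pick
  clock: 2
  instr: choose(press(left),press(right))
- thread: press(left)
  clock: 1
  instr: receive(any(cfg(A,B,C),pick),P)
- thread: press(left)
  clock: 2
  instr: act(press(left))
- thread: press(right)
  clock: 1
  instr: receive(any(cfg(A,B,C),pick),P)
- thread: press(right)
  clock: 2
  instr: act(press(right))
- thread: reward(A)
  clock: 1
  instr: emit(excite(A),ltp(A,K),ltd(J))
- thread: punish(A)
  clock: 1
  instr: emit(inhibit(A))
- thread: ltp(A,K)
  clock: 1
  instr: join(active_key(K))
- thread: ltp(A,K)
  clock: 2
  instr: inc_weight(K,A)
- thread: ltd(K)
  clock: 1
  instr: join(learn_tok(K))
- thread: ltd(K)
  clock: 2
  instr: dec_weight(K,explore(K))
stm_capacity: 1
stm_initial: []
ltm_initial: []
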