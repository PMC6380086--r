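name: rule_nmts
nodes:
- sense(left(L))
- sense(right(R))
- sense(sample(S))
- try(match(left(L),sample(S)))
- try(match(right(R),sample(S)))
- explore
- pick
- press(left)
- press(right)
- reward(A)
- punish(A)
- ltp(A,T)
- ltd(learn)
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
  - try(match(left(L),sample(S)))
- kind: synapse
  endpoints:
  - sense(right(R))
  - try(match(right(R),sample(S)))
- kind: synapse
  endpoints:
  - sense(sample(S))
  - try(match(left(L),sample(S)))
- kind: synapse
  endpoints:
  - sense(sample(S))
  - try(match(right(R),sample(S)))
- kind: synapse
  endpoints:
  - sense(sample(S))
  - explore
weights:
- p: sense(left(L))
  q: try(match(left(M),sample(S)))
  w: 1
- p: sense(right(R))
  q: try(match(right(M),sample(S)))
  w: 1
- p: sense(sample(S))
  q: try(match(A,B))
  w: 1
- p: sense(sample(S))
  q: explore
  w: 1
- p: try(match(A,B))
  q: press(X)
  w: 0
- p: explore
  q: pick
  w: 1
- p: pick
  q: press(left)
  w: 1
- p: pick
  q: press(right)
  w: 1
- p: reward(A)
  q: ltp(B,T)
  w: 1
- p: reward(A)
  q: ltd(learn)
  w: 1
rules:
- thread: try(match(left(C),sample(S)))
  clock: 1
  instr: receive(sense(sample(Z)),sample(S))
- thread: try(match(right(C),sample(S)))
  clock: 1
  instr: receive(sense(sample(Z)),sample(S))
- thread: try(match(left([C]),sample([C])))
  clock: 2
  instr: merge(matched(left([C])))
- thread: try(match(right([C]),sample([C])))
  clock: 2
  instr: merge(matched(right([C])))
- thread: try(match(left(C),sample(S)))
  clock: 2
  instr: merge(probe(try(match(left(C),sample(S)))))
- thread: try(match(right(C),sample(S)))
  clock: 2
  instr: merge(probe(try(match(right(C),sample(S)))))
- thread: try(match(left([C]),sample([C])))
  clock: 3
  instr: merge(matched_done(left([C])))
- thread: try(match(right([C]),sample([C])))
  clock: 3
  instr: merge(matched_done(right([C])))
- thread: try(match(left(C),sample(S)))
  clock: 3
  instr: emit(inhibit(match(left(C),sample(S))),press(left))
- thread: try(match(right(C),sample(S)))
  clock: 3
  instr: emit(inhibit(match(right(C),sample(S))),press(right))
- thread: explore
  clock: 1
  instr: receive(sense(sample(Z)),sample(S))
- thread: explore
  clock: 2
  instr: merge(learn_tok(explore))
- thread: explore
  clock: 3
  instr: emit(fetch(explore),pick)
- thread: pick
  clock: 1
  instr: receive(explore,fetch(F))
- thread: pick
  clock: 2
  instr: choose(press(left),press(right))
- thread: press(left)
  clock: 1
  instr: receive(any(try(match(left(C),sample(S))),pick),P)
- thread: press(left)
  clock: 2
  instr: act(press(left))
- thread: press(right)
  clock: 1
  instr: receive(any(try(match(right(C),sample(S))),pick),P)
- thread: press(right)
  clock: 2
  instr: act(press(right))
- thread: reward(press(left))
  clock: 1
  instr: emit(excite(press(left)),ltp(press(left),try(match(left(C),sample(S)))),ltd(learn))
- thread: reward(press(right))
  clock: 1
  instr: emit(excite(press(right)),ltp(press(right),try(match(right(C),sample(S)))),ltd(learn))
- thread: punish(A)
  clock: 1
  instr: emit(inhibit(A))
- thread: ltp(A,T)
  clock: 1
  instr: join(probe(T))
- thread: ltp(A,T)
  clock: 2
  instr: inc_weight(T,A)
- thread: ltd(learn)
  clock: 1
  instr: join(learn_tok(explore))
- thread: ltd(learn)
  clock: 2
  instr: dec_weight(sense(sample(Z)),explore)
stm_capacity: 1
stm_initial: []
ltm_initial: []
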