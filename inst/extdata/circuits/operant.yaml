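name: operant
nodes:
- sense(cue(C))
- ctrl(cue(C))
- explore(K)
- pick(K)
- accept(cue(C))
- reject(cue(C))
- reward(A)
- punish(A)
- ltp(A,K)
- ltd(K)
sensors:
- sense(cue(C))
effectors:
- accept(cue(C))
- reject(cue(C))
connectors:
- kind: synapse
  endpoints:
  - sense(cue(C))
  - ctrl(cue(C))
weights:
- p: sense(cue(C))
  q: ctrl(A)
  w: 1
- p: ctrl(cue(C))
  q: accept(cue(D))
  w: 0
- p: ctrl(cue(C))
  q: reject(cue(D))
  w: 0
- p: ctrl(cue(C))
  q: explore(K)
  w: 1
- p: explore(K)
  q: pick(J)
  w: 1
- p: pick(K)
  q: accept(cue(C))
  w: 1
- p: pick(K)
  q: reject(cue(C))
  w: 1
- p: reward(A)
  q: ltp(B,K)
  w: 1
- p: reward(A)
  q: ltd(K)
  w: 1
rules:
- thread: ctrl(cue(C))
  clock: 1
  instr: receive(sense(cue(Z)),cue(C))
- thread: ctrl(cue(C))
  clock: 2
  instr: send(accept(cue(C)),offer(accept))
- thread: ctrl(cue(C))
  clock: 3
  instr: send(reject(cue(C)),offer(reject))
- thread: ctrl(cue(C))
  clock: 4
  instr: merge(active_key(ctrl(cue(C))))
- thread: ctrl(cue(C))
  clock: 5
  instr: send(explore(ctrl(cue(C))),go(explore))
- thread: explore(K)
  clock: 1
  instr: receive(ctrl(A),G)
- thread: explore(K)
  clock: 2
  instr: merge(learn_tok(K))
- thread: explore(K)
  clock: 3
  instr: emit(fetch(K),pick(K))
- thread: pick(K)
  clock: 1
  instr: receive(explore(A),fetch(F))
- thread: pick(ctrl(cue(C)))
  clock: 2
  instr: choose(accept(cue(C)),reject(cue(C)))
- thread: accept(cue(C))
  clock: 1
  instr: receive(any(ctrl(A),pick(B)),P)
- thread: accept(cue(C))
  clock: 2
  instr: act(accept(cue(C)))
- thread: reject(cue(C))
  clock: 1
  instr: receive(any(ctrl(A),pick(B)),P)
- thread: reject(cue(C))
  clock: 2
  instr: act(reject(cue(C)))
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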