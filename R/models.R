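## Builders for the six model circuits.  Classical conditioning is wired
## entirely from the standard connector vocabulary; the conditioning/NMTS
## circuits add hand-written implications for their internal-stimulus layers
## (exploration by fetch/choose, deduction-based match evaluation,
## feedback-driven ltp/ltd).  The win/stay-lose/shift and categorical
## sorting circuits are reconstructions original to this package: the
## underlying experiments are modeled with nothing beyond the STM push/pull
## and LTM store/retrieve primitives.

MODEL_NAMES <- c("classical", "operant", "configural_nmts", "rule_nmts",
                 "win_stay_lose_shift", "categorical_sort")

syn <- function(p, q) list(kind = "synapse", endpoints = c(p, q))
rule <- function(thread, clock, instr) {
  list(thread = thread, clock = clock, instr = instr)
}
w0 <- function(p, q, w) list(p = p, q = q, w = w)

build_classical <- function() {
  circuit_spec(
    name = "classical",
    nodes = c("sense(cs)", "sense(us)", "motor(X)"),
    sensors = c("sense(cs)", "sense(us)"),
    effectors = "motor(X)",
    connectors = list(
      syn("sense(us)", "motor(X)"),
      syn("sense(cs)", "motor(X)"),
      list(kind = "modulation_up",
           endpoints = c("sense(us)", "sense(cs)", "motor(X)")),
      list(kind = "choice",
           endpoints = c("sense(us)", "sense(cs)", "motor(X)"))),
    weights = list(
      w0("sense(us)", "motor(X)", 1L),
      w0("sense(cs)", "motor(X)", 0L)))
}

build_operant <- function() {
  circuit_spec(
    name = "operant",
    nodes = c("sense(cue(C))", "ctrl(cue(C))", "explore(K)", "pick(K)",
              "accept(cue(C))", "reject(cue(C))",
              "reward(A)", "punish(A)", "ltp(A,K)", "ltd(K)"),
    sensors = "sense(cue(C))",
    effectors = c("accept(cue(C))", "reject(cue(C))"),
    connectors = list(syn("sense(cue(C))", "ctrl(cue(C))")),
    weights = list(
      w0("sense(cue(C))", "ctrl(A)", 1L),
      w0("ctrl(cue(C))", "accept(cue(D))", 0L),
      w0("ctrl(cue(C))", "reject(cue(D))", 0L),
      w0("ctrl(cue(C))", "explore(K)", 1L),
      w0("explore(K)", "pick(J)", 1L),
      w0("pick(K)", "accept(cue(C))", 1L),
      w0("pick(K)", "reject(cue(C))", 1L),
      w0("reward(A)", "ltp(B,K)", 1L),
      w0("reward(A)", "ltd(K)", 1L)),
    rules = list(
      rule("ctrl(cue(C))", 1, "receive(sense(cue(Z)),cue(C))"),
      rule("ctrl(cue(C))", 2, "send(accept(cue(C)),offer(accept))"),
      rule("ctrl(cue(C))", 3, "send(reject(cue(C)),offer(reject))"),
      rule("ctrl(cue(C))", 4, "merge(active_key(ctrl(cue(C))))"),
      rule("ctrl(cue(C))", 5, "send(explore(ctrl(cue(C))),go(explore))"),
      rule("explore(K)", 1, "receive(ctrl(A),G)"),
      rule("explore(K)", 2, "merge(learn_tok(K))"),
      rule("explore(K)", 3, "emit(fetch(K),pick(K))"),
      rule("pick(K)", 1, "receive(explore(A),fetch(F))"),
      rule("pick(ctrl(cue(C)))", 2, "choose(accept(cue(C)),reject(cue(C)))"),
      rule("accept(cue(C))", 1, "receive(any(ctrl(A),pick(B)),P)"),
      rule("accept(cue(C))", 2, "act(accept(cue(C)))"),
      rule("reject(cue(C))", 1, "receive(any(ctrl(A),pick(B)),P)"),
      rule("reject(cue(C))", 2, "act(reject(cue(C)))"),
      rule("reward(A)", 1, "emit(excite(A),ltp(A,K),ltd(J))"),
      rule("punish(A)", 1, "emit(inhibit(A))"),
      rule("ltp(A,K)", 1, "join(active_key(K))"),
      rule("ltp(A,K)", 2, "inc_weight(K,A)"),
      rule("ltd(K)", 1, "join(learn_tok(K))"),
      rule("ltd(K)", 2, "dec_weight(K,explore(K))")))
}

## the four distinct-button NMTS configurations over a two-color palette
nmts_configs <- function(palette = c("red", "green")) {
  out <- list()
  for (l in palette) for (r in palette) for (s in palette) {
    if (l != r && s %in% c(l, r)) {
      out[[length(out) + 1L]] <- c(left = l, right = r, sample = s)
    }
  }
  out
}

build_configural_nmts <- function(palette = c("red", "green")) {
  weights <- list(
    w0("sense(left(L))", "cfg(A,B,C)", 1L),
    w0("sense(right(R))", "cfg(A,B,C)", 1L),
    w0("sense(sample(S))", "cfg(A,B,C)", 1L),
    w0("explore(K)", "pick", 1L),
    w0("pick", "press(left)", 1L),
    w0("pick", "press(right)", 1L),
    w0("reward(A)", "ltp(B,K)", 1L),
    w0("reward(A)", "ltd(K)", 1L))
  ## configural learning = one ground pathway triple per stimulus
  ## configuration: the response links and the exploration gate are
  ## configuration-specific, so nothing learned transfers to a novel one
  for (cf in nmts_configs(palette)) {
    key <- sprintf("cfg(left([%s]),right([%s]),sample([%s]))",
                   cf[["left"]], cf[["right"]], cf[["sample"]])
    weights <- c(weights, list(
      w0(key, "press(left)", 0L),
      w0(key, "press(right)", 0L),
      w0(key, sprintf("explore(%s)", key), 1L)))
  }
  circuit_spec(
    name = "configural_nmts",
    nodes = c("sense(left(L))", "sense(right(R))", "sense(sample(S))",
              "cfg(left(L),right(R),sample(S))", "explore(K)", "pick",
              "press(left)", "press(right)",
              "reward(A)", "punish(A)", "ltp(A,K)", "ltd(K)"),
    sensors = c("sense(left(L))", "sense(right(R))", "sense(sample(S))"),
    effectors = c("press(left)", "press(right)"),
    connectors = list(
      syn("sense(left(L))", "cfg(left(L),right(R),sample(S))"),
      syn("sense(right(R))", "cfg(left(L),right(R),sample(S))"),
      syn("sense(sample(S))", "cfg(left(L),right(R),sample(S))")),
    weights = weights,
    rules = list(
      rule("cfg(left(L),right(R),sample(S))", 1, "receive(sense(left(Z)),left(L))"),
      rule("cfg(left(L),right(R),sample(S))", 2, "receive(sense(right(Z)),right(R))"),
      rule("cfg(left(L),right(R),sample(S))", 3, "receive(sense(sample(Z)),sample(S))"),
      rule("cfg(left(L),right(R),sample(S))", 4, "send(press(left),offer(left))"),
      rule("cfg(left(L),right(R),sample(S))", 5, "send(press(right),offer(right))"),
      rule("cfg(left(L),right(R),sample(S))", 6,
           "merge(active_key(cfg(left(L),right(R),sample(S))))"),
      rule("cfg(left(L),right(R),sample(S))", 7,
           "send(explore(cfg(left(L),right(R),sample(S))),go(explore))"),
      rule("explore(K)", 1, "receive(cfg(A,B,C),G)"),
      rule("explore(K)", 2, "merge(learn_tok(K))"),
      rule("explore(K)", 3, "emit(fetch(K),pick)"),
      rule("pick", 1, "receive(explore(K),fetch(F))"),
      rule("pick", 2, "choose(press(left),press(right))"),
      rule("press(left)", 1, "receive(any(cfg(A,B,C),pick),P)"),
      rule("press(left)", 2, "act(press(left))"),
      rule("press(right)", 1, "receive(any(cfg(A,B,C),pick),P)"),
      rule("press(right)", 2, "act(press(right))"),
      rule("reward(A)", 1, "emit(excite(A),ltp(A,K),ltd(J))"),
      rule("punish(A)", 1, "emit(inhibit(A))"),
      rule("ltp(A,K)", 1, "join(active_key(K))"),
      rule("ltp(A,K)", 2, "inc_weight(K,A)"),
      rule("ltd(K)", 1, "join(learn_tok(K))"),
      rule("ltd(K)", 2, "dec_weight(K,explore(K))")))
}

build_rule_nmts <- function() {
  circuit_spec(
    name = "rule_nmts",
    nodes = c("sense(left(L))", "sense(right(R))", "sense(sample(S))",
              "try(match(left(L),sample(S)))", "try(match(right(R),sample(S)))",
              "explore", "pick", "press(left)", "press(right)",
              "reward(A)", "punish(A)", "ltp(A,T)", "ltd(learn)"),
    sensors = c("sense(left(L))", "sense(right(R))", "sense(sample(S))"),
    effectors = c("press(left)", "press(right)"),
    connectors = list(
      syn("sense(left(L))", "try(match(left(L),sample(S)))"),
      syn("sense(right(R))", "try(match(right(R),sample(S)))"),
      syn("sense(sample(S))", "try(match(left(L),sample(S)))"),
      syn("sense(sample(S))", "try(match(right(R),sample(S)))"),
      syn("sense(sample(S))", "explore")),
    weights = list(
      w0("sense(left(L))", "try(match(left(M),sample(S)))", 1L),
      w0("sense(right(R))", "try(match(right(M),sample(S)))", 1L),
      w0("sense(sample(S))", "try(match(A,B))", 1L),
      w0("sense(sample(S))", "explore", 1L),       # the exploration gate, closed by ltd
      ## the avoid-route: a single relational pathway from refuted-match
      ## hypotheses to the corresponding button; ltp on it opens the route
      ## for both sides at once, which is what lets the rule transfer
      w0("try(match(A,B))", "press(X)", 0L),
      w0("explore", "pick", 1L),
      w0("pick", "press(left)", 1L),
      w0("pick", "press(right)", 1L),
      w0("reward(A)", "ltp(B,T)", 1L),
      w0("reward(A)", "ltd(learn)", 1L)),
    rules = list(
      ## the match layer: receive the sample, evaluate the coincidence of
      ## the two colors by deduction (the repeated-variable heads are
      ## declared first and capture structural equality), then either stop
      ## silently (match) or emit the inhibit of the refuted match
      ## hypothesis toward that side's button (non-match)
      rule("try(match(left(C),sample(S)))", 1, "receive(sense(sample(Z)),sample(S))"),
      rule("try(match(right(C),sample(S)))", 1, "receive(sense(sample(Z)),sample(S))"),
      rule("try(match(left([C]),sample([C])))", 2, "merge(matched(left([C])))"),
      rule("try(match(right([C]),sample([C])))", 2, "merge(matched(right([C])))"),
      rule("try(match(left(C),sample(S)))", 2,
           "merge(probe(try(match(left(C),sample(S)))))"),
      rule("try(match(right(C),sample(S)))", 2,
           "merge(probe(try(match(right(C),sample(S)))))"),
      rule("try(match(left([C]),sample([C])))", 3, "merge(matched_done(left([C])))"),
      rule("try(match(right([C]),sample([C])))", 3, "merge(matched_done(right([C])))"),
      rule("try(match(left(C),sample(S)))", 3,
           "emit(inhibit(match(left(C),sample(S))),press(left))"),
      rule("try(match(right(C),sample(S)))", 3,
           "emit(inhibit(match(right(C),sample(S))),press(right))"),
      ## exploration layer (operant base): open until ltd closes it
      rule("explore", 1, "receive(sense(sample(Z)),sample(S))"),
      rule("explore", 2, "merge(learn_tok(explore))"),
      rule("explore", 3, "emit(fetch(explore),pick)"),
      rule("pick", 1, "receive(explore,fetch(F))"),
      rule("pick", 2, "choose(press(left),press(right))"),
      rule("press(left)", 1, "receive(any(try(match(left(C),sample(S))),pick),P)"),
      rule("press(left)", 2, "act(press(left))"),
      rule("press(right)", 1, "receive(any(try(match(right(C),sample(S))),pick),P)"),
      rule("press(right)", 2, "act(press(right))"),
      ## reward feedback: the ltp detector joins the probe token posted by
      ## the non-matching try thread, so the avoid-route only opens when
      ## the rewarded choice was the refuted-match side; the pathway is
      ## declared at pattern level, which is what makes the rule transfer
      rule("reward(press(left))", 1,
           "emit(excite(press(left)),ltp(press(left),try(match(left(C),sample(S)))),ltd(learn))"),
      rule("reward(press(right))", 1,
           "emit(excite(press(right)),ltp(press(right),try(match(right(C),sample(S)))),ltd(learn))"),
      rule("punish(A)", 1, "emit(inhibit(A))"),
      rule("ltp(A,T)", 1, "join(probe(T))"),
      rule("ltp(A,T)", 2, "inc_weight(T,A)"),
      rule("ltd(learn)", 1, "join(learn_tok(explore))"),
      rule("ltd(learn)", 2, "dec_weight(sense(sample(Z)),explore)")))
}

build_win_stay_lose_shift <- function() {
  circuit_spec(
    name = "win_stay_lose_shift",
    nodes = c("sense(go)", "wsls(last(A,B))", "pick",
              "press(left)", "press(right)", "reward(A)", "punish(A)"),
    sensors = "sense(go)",
    effectors = c("press(left)", "press(right)"),
    connectors = list(syn("sense(go)", "wsls(last(A,B))")),
    weights = list(
      w0("sense(go)", "wsls(A)", 1L),
      w0("wsls(A)", "press(X)", 1L),
      w0("wsls(A)", "pick", 1L),
      w0("pick", "press(X)", 1L)),
    rules = list(
      rule("wsls(last(A,B))", 1, "receive(sense(go),G)"),
      rule("wsls(last(A,B))", 2, "pull(last(A,B))"),
      ## the strategy itself, by deduction over the recalled last trial
      rule("wsls(last(A,win))", 3, "send(press(A),go(press(A)))"),
      rule("wsls(last(left,lose))", 3, "send(press(right),go(press(right)))"),
      rule("wsls(last(right,lose))", 3, "send(press(left),go(press(left)))"),
      rule("wsls(last(none,none))", 3, "emit(fetch(wsls),pick)"),
      rule("pick", 1, "receive(wsls(A),fetch(F))"),
      rule("pick", 2, "choose(press(left),press(right))"),
      rule("press(left)", 1, "receive(any(wsls(A),pick),P)"),
      rule("press(left)", 2, "act(press(left))"),
      rule("press(right)", 1, "receive(any(wsls(A),pick),P)"),
      rule("press(right)", 2, "act(press(right))"),
      rule("reward(press(B))", 1, "emit(excite(press(B)))"),
      rule("reward(press(B))", 2, "push(last(B,win))"),
      rule("punish(press(B))", 1, "emit(inhibit(press(B)))"),
      rule("punish(press(B))", 2, "push(last(B,lose))")),
    stm_capacity = 1L,
    stm_initial = "last(none,none)")
}

build_categorical_sort <- function() {
  circuit_spec(
    name = "categorical_sort",
    nodes = c("sense(study(item(N),color(C)))", "sense(assign(color(C),bin(B)))",
              "sense(sort(item(N)))", "scribe(item(N),color(C))",
              "binder(color(C),bin(B))", "sorter(item(N),C,B)"),
    sensors = c("sense(study(item(N),color(C)))",
                "sense(assign(color(C),bin(B)))", "sense(sort(item(N)))"),
    effectors = character(),
    connectors = list(
      syn("sense(study(item(N),color(C)))", "scribe(item(N),color(C))"),
      syn("sense(assign(color(C),bin(B)))", "binder(color(C),bin(B))"),
      syn("sense(sort(item(N)))", "sorter(item(N),C,B)")),
    weights = list(
      w0("sense(study(item(N),color(C)))", "scribe(A,B)", 1L),
      w0("sense(assign(color(C),bin(B)))", "binder(A,B)", 1L),
      w0("sense(sort(item(N)))", "sorter(A,B,C)", 1L)),
    rules = list(
      rule("scribe(item(N),color(C))", 1, "receive(sense(A),P)"),
      rule("scribe(item(N),color(C))", 2, "store(color(item(N),C))"),
      rule("binder(color(C),bin(B))", 1, "receive(sense(A),P)"),
      rule("binder(color(C),bin(B))", 2, "store(category(C,bin(B)))"),
      ## the categorical judgment integrates two stored sets: the item's
      ## color and the color's bin assignment
      rule("sorter(item(N),C,B)", 1, "receive(sense(A),P)"),
      rule("sorter(item(N),C,B)", 2, "retrieve(color(item(N),C))"),
      rule("sorter(item(N),C,B)", 3, "retrieve(category(C,bin(B)))"),
      rule("sorter(item(N),C,B)", 4, "act(put(item(N),bin(B)))")))
}

#' Build one of the six model circuits
#'
#' Returns the wired circuit for one of the behavioral models: `classical`
#' (conditioning with an ltp facilitatory interneuron), `operant`
#' (excite/inhibit feedback opening accept or reject and closing the
#' exploratory route), `configural_nmts` (non-matching-to-sample solved by
#' memorizing one response per stimulus configuration), `rule_nmts`
#' (non-matching-to-sample solved by learning to match colors and avoiding
#' the match; two additional layers over the operant base),
#' `win_stay_lose_shift` (a strategy recalled from the short-term cache)
#' and `categorical_sort` (sorting by integrating two sets of long-term
#' memory facts).  The last two are reconstructions original to this
#' package, built from the STM and LTM primitives.
#'
#' @param name one of `"classical"`, `"operant"`, `"configural_nmts"`,
#'   `"rule_nmts"`, `"win_stay_lose_shift"`, `"categorical_sort"`.
#' @param palette color palette for the NMTS circuits.
#' @return A [circuit_spec()]; compile with [compile_circuit()].
#' @export
build_model <- function(name = MODEL_NAMES, palette = c("red", "green")) {
  name <- match.arg(name)
  switch(name,
         classical = build_classical(),
         operant = build_operant(),
         configural_nmts = build_configural_nmts(palette),
         rule_nmts = build_rule_nmts(),
         win_stay_lose_shift = build_win_stay_lose_shift(),
         categorical_sort = build_categorical_sort())
}
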