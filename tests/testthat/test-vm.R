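# Machine-core semantics: contextual deduction, stepping, scheduling,
# presentation cycles, determinism and the structural invariants.

rule_model <- function() compile_circuit(build_model("rule_nmts"))
classical_model <- function() compile_circuit(build_model("classical"))

test_that("deduction returns the first matching implication, instantiated", {
  m <- rule_model()
  st <- new_machine(m)
  th <- spawn_thread(st, "try(match(left([green]),sample([red])))")
  th$clock <- 3L
  instr <- deduce_instruction(th, m, st)
  expect_identical(instr$opcode, "emit")
  expect_identical(term_format(instr$operands[[1L]]),
                   "inhibit(match(left([green]),sample([red])))")
  ## the equal-colors head is declared first and shadows the generic one
  th2 <- spawn_thread(st, "try(match(right([red]),sample([red])))")
  th2$clock <- 3L
  instr2 <- deduce_instruction(th2, m, st)
  expect_identical(instr2$opcode, "merge")
})

test_that("deduction is none when the tree is exhausted or nothing matches", {
  m <- rule_model()
  st <- new_machine(m)
  th <- spawn_thread(st, "try(match(left([green]),sample([red])))")
  th$clock <- 9L
  expect_null(deduce_instruction(th, m, st))
  th2 <- spawn_thread(st, "nonexistent(thing)")
  expect_null(deduce_instruction(th2, m, st))
  expect_identical(step_thread(st, th2), "finished")
  expect_identical(th2$status, "done")
})

test_that("a gated receive blocks on an empty queue and advances once fed", {
  m <- classical_model()
  st <- new_machine(m)
  st$presentation <- 1L
  recv <- spawn_thread(st, "motor(X)")
  expect_identical(step_thread(st, recv), "retry")
  expect_identical(recv$clock, 1L)
  sender <- spawn_thread(st, "sense(us)")
  sender$clock <- 3L                      # at its send instruction
  expect_identical(step_thread(st, sender), "advanced")
  expect_identical(step_thread(st, recv), "advanced")
  expect_identical(recv$clock, 2L)
  expect_identical(term_format(recv$id), "motor(us)")
})

test_that("a closed gate retains the signal rather than consuming it", {
  m <- classical_model()
  st <- new_machine(m)
  st$presentation <- 1L
  recv <- spawn_thread(st, "motor(X)")
  sender <- spawn_thread(st, "sense(cs)")  # pathway weight 0: gate closed
  sender$clock <- 3L
  step_thread(st, sender)
  expect_length(st$signals, 1L)
  expect_identical(step_thread(st, recv), "retry")
  expect_length(st$signals, 1L)            # retained, not consumed
  adjust_weight(st$weights, "sense(cs)", "motor(X)", 1L)
  expect_identical(step_thread(st, recv), "advanced")
  expect_length(st$signals, 0L)
  expect_identical(term_format(recv$id), "motor(cs)")
})

test_that("send fires the receiver once and queues FIFO", {
  m <- classical_model()
  st <- new_machine(m)
  st$presentation <- 1L
  a <- spawn_thread(st, "sense(us)")
  a$clock <- 3L
  b <- spawn_thread(st, "sense(cs)")
  b$clock <- 3L
  step_thread(st, a)                       # spawns motor(X)
  n <- length(st$threads)
  step_thread(st, b)                       # existing receiver: no respawn
  expect_length(st$threads, n)
  expect_length(st$signals, 2L)
  expect_identical(term_format(st$signals[[1L]]$payload), "us")
  expect_identical(term_format(st$signals[[2L]]$payload), "cs")
})

test_that("merge posts tokens consumed at most once by join, any order", {
  m <- classical_model()
  cfgs <- list(c("merge", "join"), c("join", "merge"))
  for (order_ in cfgs) {
    st <- new_machine(m)
    st$presentation <- 1L
    q <- spawn_thread(st, "sense(cs)")
    q$clock <- 2L                          # at its merge instruction
    ltp <- spawn_thread(st, "ltp(sense(cs),motor(X))")
    outcomes <- character()
    for (who in order_) {
      outcomes[[length(outcomes) + 1L]] <-
        if (who == "merge") step_thread(st, q) else step_thread(st, ltp)
    }
    if (order_[1L] == "join") {
      expect_identical(outcomes, c("retry", "advanced"))
      expect_identical(step_thread(st, ltp), "advanced")
    } else {
      expect_identical(outcomes, c("advanced", "advanced"))
    }
    expect_length(st$tokens, 0L)           # single consumption
  }
})

test_that("coincidence outcome is identical under every interleaving", {
  ## replay-based exhaustive enumeration of scheduler interleavings for the
  ## ltp microcircuit: P fires ltp, Q merges then sends R, ltp joins then
  ## increments weight(Q, R); no-op (blocked) steps are pruned since they
  ## leave the state unchanged
  m <- compile_circuit(circuit_spec(
    name = "ltp_micro",
    nodes = c("sense(p)", "sense(q)", "out(X)"),
    sensors = c("sense(p)", "sense(q)"), effectors = "out(X)",
    connectors = list(
      list(kind = "synapse", endpoints = c("sense(q)", "out(X)")),
      list(kind = "modulation_up",
           endpoints = c("sense(p)", "sense(q)", "out(X)"))),
    weights = list(list(p = "sense(q)", q = "out(X)", w = 0L))))
  clone_env <- function(e, cls) {
    e2 <- new.env(parent = emptyenv())
    for (n in ls(e, all.names = TRUE)) assign(n, get(n, envir = e), envir = e2)
    class(e2) <- cls
    e2
  }
  clone_state <- function(st) {
    s2 <- clone_env(st, "machine_state")
    s2$threads <- lapply(st$threads, clone_env, cls = "vm_thread")
    s2$weights <- clone_env(st$weights, "weight_table")
    s2
  }
  state_key <- function(st) {
    ths <- vapply(st$threads, function(t) {
      paste(t$spawn_id, term_format(t$id), t$clock, t$status, sep = "|")
    }, "")
    paste(c(sort(ths), "S:",
            vapply(st$signals, function(s) term_format(s$payload), ""),
            "T:", vapply(st$tokens, term_format, ""),
            "W:", st$weights$w), collapse = ";")
  }
  start <- local({
    st <- new_machine(m)
    st$presentation <- 1L
    spawn_thread(st, "sense(p)")
    spawn_thread(st, "sense(q)")
    st
  })
  visited <- new.env(parent = emptyenv())
  finals <- integer()
  n_states <- 0L
  walk <- function(st) {
    k <- state_key(st)
    if (!is.null(visited[[k]])) return(invisible(NULL))
    visited[[k]] <- TRUE
    n_states <<- n_states + 1L
    progressed <- FALSE
    for (th in Filter(function(t) t$status == "active", st$threads)) {
      s2 <- clone_state(st)
      th2 <- Filter(function(t) t$spawn_id == th$spawn_id, s2$threads)[[1L]]
      out <- step_thread(s2, th2)
      if (out == "retry") next   # no-op: leaves the state unchanged
      progressed <- TRUE
      walk(s2)
    }
    if (!progressed) {
      finals[[length(finals) + 1L]] <<-
        weight_lookup(st$weights, "sense(q)", "out(x)")
    }
  }
  walk(start)
  expect_gt(n_states, 10L)
  expect_gt(length(finals), 0L)
  expect_true(all(finals == 1L))
})

test_that("presentation cycles number streams from 1 in activation order", {
  m <- rule_model()
  res <- vm_run(m, rep(list("sensor(left([green]),right([red]),sample([red]))"), 3))
  st <- res$state
  for (p in 1:3) {
    cyc <- res$trace[res$trace$presentation == p, ]
    expect_true(all(cyc$stream_seq >= 1L & cyc$stream_seq <= st$stream_log[p]))
    caps <- cyc[cyc$event_kind == "sensor_capture", "stream_seq"]
    expect_identical(caps, 1:3)            # element order = activation order
  }
})

test_that("an empty input vector yields an empty trace and no state change", {
  m <- rule_model()
  res <- vm_run(m, list("sensor"))
  expect_identical(nrow(res$trace), 0L)
  expect_identical(weight_dump(new_machine(m)$weights),
                   weight_dump(res$state$weights))
})

test_that("runs are deterministic: same seed, byte-identical serialized traces", {
  for (seed in c(1L, 7L)) {
    cfg <- experiment_config("configural_nmts", n_presentations = 8L,
                             seed = seed)
    p1 <- withr::local_tempfile(fileext = ".jsonl")
    p2 <- withr::local_tempfile(fileext = ".jsonl")
    run_experiment(cfg, trace_path = p1)
    run_experiment(cfg, trace_path = p2)
    expect_identical(readLines(p1), readLines(p2))
  }
})

test_that("thread clocks are monotone and advance by exactly one", {
  cfg <- experiment_config("rule_nmts", n_presentations = 6L, seed = 2L)
  res <- run_experiment(cfg)
  tr <- res$trace
  for (p in unique(tr$presentation)) {
    cyc <- tr[tr$presentation == p, ]
    for (th in unique(cyc$thread)) {
      lt <- cyc$local_time[cyc$thread == th]
      expect_true(all(diff(lt) >= 0L))
    }
  }
})

test_that("an idle extra sensor never perturbs other threads' trajectories", {
  base <- build_model("rule_nmts")
  noisy <- base
  noisy$nodes <- c(noisy$nodes, "sense(noise(N))")
  noisy$sensors <- c(noisy$sensors, "sense(noise(N))")
  m0 <- compile_circuit(base)
  m1 <- compile_circuit(noisy)
  input0 <- "sensor(left([green]),right([red]),sample([red]))"
  input1 <- "sensor(left([green]),right([red]),sample([red]),noise(z))"
  r0 <- vm_run(m0, rep(list(input0), 4))
  r1 <- vm_run(m1, rep(list(input1), 4))
  t1 <- r1$trace[r1$trace$thread != "sense(noise(z))", ]
  rownames(t1) <- NULL
  expect_identical(r0$trace, t1, ignore_attr = TRUE)
})

test_that("a circular wait terminates the cycle with a diagnostic", {
  m <- compile_circuit(circuit_spec(
    name = "deadlock2",
    nodes = c("sense(a)", "wait1", "wait2"),
    sensors = "sense(a)",
    connectors = list(
      list(kind = "synapse", endpoints = c("sense(a)", "wait1")),
      list(kind = "synapse", endpoints = c("sense(a)", "wait2"))),
    weights = list(list(p = "sense(a)", q = "wait1", w = 1L),
                   list(p = "sense(a)", q = "wait2", w = 1L)),
    rules = list(
      list(thread = "wait1", clock = 1, instr = "receive(sense(Z),P)"),
      list(thread = "wait1", clock = 2, instr = "join(tok_from_2(X))"),
      list(thread = "wait2", clock = 1, instr = "receive(sense(Z),P)"),
      list(thread = "wait2", clock = 2, instr = "join(tok_from_1(X))"))))
  res <- vm_run(m, list("sensor(a)"))
  expect_length(res$state$diagnostics, 1L)
  expect_match(res$state$diagnostics[[1L]], "2 blocked thread")
})

test_that("the per-cycle step budget aborts runaway cycles with partial trace", {
  m <- rule_model()
  cnd <- tryCatch(
    vm_run(m, list("sensor(left([green]),right([red]),sample([red]))"),
           vm_config(max_steps_per_cycle = 5L)),
    fibervm_budget_error = function(e) e)
  expect_s3_class(cnd, "fibervm_budget_error")
  expect_true(is.data.frame(cnd$trace))
})

test_that("signals are conserved: sent = consumed + cleared at cycle end", {
  cfg <- experiment_config("rule_nmts", n_presentations = 10L, seed = 3L)
  res <- run_experiment(cfg)
  st <- res$state
  expect_identical(st$n_sent, st$n_consumed + st$n_cleared)
})
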