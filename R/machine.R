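## Virtual machine core: threads with local clocks, contextual deduction of
## instructions from (identity, clock), a deterministic cooperative
## scheduler, and the sense-act-reflect presentation cycle.

VM_OPCODES <- c("fire", "capture", "send", "receive", "join", "merge",
                "push", "pull", "store", "retrieve", "inc_weight",
                "dec_weight", "choose", "act", "emit")

#' Virtual machine run configuration
#'
#' @param seed integer seed for the machine's own pseudo-random generator
#'   (the only consumer is the `choose` instruction).
#' @param threshold integer weight-gate threshold; a receive proceeds only
#'   when the pathway weight is strictly above it.
#' @param delta_ltp,delta_ltd integer weight increments applied by
#'   `inc_weight` / `dec_weight`.
#' @param w_min,w_max clamp range for weights.
#' @param max_steps_per_cycle per-cycle budget of instruction attempts
#'   (blocked instructions retry until the cycle quiesces or the budget is
#'   exhausted).
#' @param stability_window number of identical consecutive cycle signatures
#'   required to call a trace suffix persistent.
#' @param feedback_fn optional function(state, cycle_trace, input) returning
#'   a list of thread identities to fire as internal feedback after the act
#'   phase quiesces (used by the experiment harness to inject reward
#'   stimuli), or NULL.
#' @return A list of class `vm_config`.
#' @export
vm_config <- function(seed = 1L, threshold = 0L, delta_ltp = 1L,
                      delta_ltd = -1L, w_min = -5L, w_max = 5L,
                      max_steps_per_cycle = 10000L, stability_window = 5L,
                      feedback_fn = NULL) {
  structure(list(seed = as.integer(seed), threshold = as.integer(threshold),
                 delta_ltp = as.integer(delta_ltp),
                 delta_ltd = as.integer(delta_ltd),
                 w_min = as.integer(w_min), w_max = as.integer(w_max),
                 max_steps_per_cycle = as.integer(max_steps_per_cycle),
                 stability_window = as.integer(stability_window),
                 feedback_fn = feedback_fn),
            class = "vm_config")
}

## Park-Miller minimal-standard generator; exact in doubles, owned by the
## machine state so R's global RNG is never consulted.
lcg_seed <- function(seed) (abs(as.numeric(seed)) %% 2147483646) + 1
lcg_next <- function(state) {
  state$rng <- (16807 * state$rng) %% 2147483647
  state$rng / 2147483647
}

#' Create a machine state for a compiled model
#'
#' The machine state bundles the thread set, signal queues, merge tokens,
#' the plastic weight table, the short- and long-term memories and the
#' trace accumulator.  Machine evolution is a pure function of
#' (initial state, input sequence, seed).
#'
#' @param model a [compile_circuit()] result.
#' @param config a [vm_config()].
#' @return A `machine_state` environment.
#' @export
new_machine <- function(model, config = vm_config()) {
  stopifnot(inherits(model, "compiled_model"))
  st <- new.env(parent = emptyenv())
  st$model <- model
  st$config <- config
  st$weights <- weight_table(model$weights, threshold = config$threshold,
                             w_min = config$w_min, w_max = config$w_max)
  st$stm <- stm_cache(model$stm_capacity, model$stm_initial)
  st$ltm <- ltm_store_new(model$ltm_initial)
  st$threads <- list()
  st$signals <- list()
  st$tokens <- list()
  st$trace <- list()
  st$presentation <- 0L
  st$fiber_count <- 0L
  st$spawn_count <- 0L
  st$var_count <- 0L
  st$rng <- lcg_seed(config$seed)
  st$steps_this_cycle <- 0L
  st$diagnostics <- character()
  st$n_sent <- 0L
  st$n_consumed <- 0L
  st$n_cleared <- 0L
  st$gate_log <- integer()
  st$plasticity_log <- list()
  st$stream_log <- integer()
  st$reward_log <- list()
  class(st) <- "machine_state"
  st
}

#' @export
print.machine_state <- function(x, ...) {
  cat("<machine_state>", length(x$threads), "threads,",
      x$presentation, "presentations,", length(x$trace), "trace records\n")
  invisible(x)
}

fresh_suffix <- function(state) {
  state$var_count <- state$var_count + 1L
  state$var_count
}

#' Spawn a thread
#'
#' A thread is a named concurrent unit: an identity term, a local clock
#' starting at 1, a fiber it belongs to and a status.  When `fiber` is NULL
#' a new fiber is opened and receives the next stream sequence number of the
#' current presentation cycle (numbering restarts at 1 each cycle).
#'
#' @param state a [new_machine()] state.
#' @param identity thread identity term (or canonical string).
#' @param fiber integer fiber id, or NULL to open a new fiber.
#' @return the thread environment, invisibly.
#' @export
spawn_thread <- function(state, identity, fiber = NULL) {
  if (is.null(fiber)) {
    state$fiber_count <- state$fiber_count + 1L
    fiber <- state$fiber_count
  }
  th <- new.env(parent = emptyenv())
  th$id <- term(identity)
  th$clock <- 1L
  th$fiber <- as.integer(fiber)
  th$status <- "active"
  state$spawn_count <- state$spawn_count + 1L
  th$spawn_id <- state$spawn_count
  class(th) <- "vm_thread"
  state$threads[[length(state$threads) + 1L]] <- th
  invisible(th)
}

live_thread_matching <- function(state, pattern) {
  for (th in state$threads) {
    if (th$status == "done") next
    if (!is.null(unify(pattern, th$id))) return(th)
  }
  NULL
}

## "thread P fires thread Q if necessary": spawn only when no live thread's
## identity unifies with the pattern; the new thread inherits its spawner's
## fiber.
spawn_if_needed <- function(state, pattern, fiber) {
  th <- live_thread_matching(state, pattern)
  if (is.null(th)) th <- spawn_thread(state, pattern, fiber = fiber)
  th
}

record_trace <- function(state, thread, kind, event) {
  state$trace[[length(state$trace) + 1L]] <- list(
    presentation = state$presentation,
    stream_seq = thread$fiber,
    thread = term_format(thread$id),
    local_time = thread$clock,
    event_kind = kind,
    event = term_format(event))
  invisible(NULL)
}

## --- contextual deduction -------------------------------------------------

#' Deduce the next instruction for a thread
#'
#' Implements contextual deduction: the first implication (in declaration
#' order) whose head unifies with the thread's (identity, clock) supplies
#' the instruction, with the unifier applied.  Returns NULL when no head
#' matches, in which case the thread's instruction tree is exhausted.
#'
#' @param thread a thread spawned by [spawn_thread()].
#' @param model a compiled model.
#' @param state machine state (used only for fresh variable renaming; a
#'   plain counter environment also works).
#' @return a list `(opcode, operands)` or NULL.
#' @export
deduce_instruction <- function(thread, model, state) {
  key <- paste0(term(thread$id)$functor, "/", thread$clock)
  idx <- model$index[[key]]
  if (is.null(idx)) return(NULL)
  for (i in idx) {
    imp <- model$implications[[i]]
    sfx <- fresh_suffix(state)
    head <- term_rename(imp$head, sfx)
    s <- unify(head, thread$id)
    if (is.null(s)) next
    ops <- lapply(imp$instr$operands, function(o) {
      apply_subst(term_rename(o, sfx), s)
    })
    return(list(opcode = imp$instr$opcode, operands = ops))
  }
  NULL
}

## --- instruction execution ------------------------------------------------

exec_send <- function(state, thread, receiver, payload) {
  if (!weight_declared(state$weights, thread$id, receiver)) {
    stop("send from ", term_format(thread$id), " to undeclared pathway ",
         term_format(receiver))
  }
  spawn_if_needed(state, receiver, fiber = thread$fiber)
  state$signals[[length(state$signals) + 1L]] <- list(
    sender = thread$id, receiver = receiver, payload = payload)
  state$n_sent <- state$n_sent + 1L
  invisible(NULL)
}

exec_receive <- function(state, thread, sender_pat, bind_pat) {
  pats <- if (is_term(sender_pat) && sender_pat$functor == "any") {
    sender_pat$args
  } else {
    list(sender_pat)
  }
  for (k in seq_along(state$signals)) {
    sig <- state$signals[[k]]
    if (is.null(unify(sig$receiver, thread$id))) next
    s <- NULL
    for (p in pats) {
      s <- unify(p, sig$sender)
      if (!is.null(s)) break
    }
    if (is.null(s)) next
    s <- unify(bind_pat, sig$payload, s)
    if (is.null(s)) next
    w <- weight_lookup(state$weights, sig$sender, thread$id)
    if (w <= state$weights$threshold) next  # gate closed: signal retained
    state$signals[[k]] <- NULL
    state$n_consumed <- state$n_consumed + 1L
    state$gate_log[[length(state$gate_log) + 1L]] <- w
    return(list(status = "ok", bind = s))
  }
  list(status = "block")
}

exec_join <- function(state, thread, pattern) {
  for (k in seq_along(state$tokens)) {
    s <- unify(pattern, state$tokens[[k]])
    if (!is.null(s)) {
      state$tokens[[k]] <- NULL
      return(list(status = "ok", bind = s))
    }
  }
  list(status = "block")
}

exec_adjust <- function(state, thread, p, q, delta) {
  w <- adjust_weight(state$weights, p, q, delta)
  state$plasticity_log[[length(state$plasticity_log) + 1L]] <- list(
    presentation = state$presentation,
    p = term_format(p), q = term_format(q),
    delta = as.integer(delta), weight = w)
  w
}

exec_choose <- function(state, thread, alts) {
  open <- Filter(function(a) {
    weight_lookup(state$weights, thread$id, a) > state$weights$threshold
  }, alts)
  if (length(open) == 0L) return(list(status = "block"))
  r <- lcg_next(state)
  pick <- open[[min(length(open), floor(r * length(open)) + 1L)]]
  exec_send(state, thread, pick, vm_term("go", list(pick)))
  list(status = "ok")
}

exec_instruction <- function(state, thread, instr) {
  op <- instr$opcode
  ops <- instr$operands
  need <- function(n) {
    if (length(ops) < n) {
      stop("malformed ", op, " instruction in thread ",
           term_format(thread$id), " at clock ", thread$clock)
    }
  }
  switch(op,
    capture = {
      need(1L)
      record_trace(state, thread, "sensor_capture", ops[[1L]])
      list(status = "ok")
    },
    send = {
      need(2L)
      exec_send(state, thread, ops[[1L]], ops[[2L]])
      list(status = "ok")
    },
    receive = {
      need(2L)
      exec_receive(state, thread, ops[[1L]], ops[[2L]])
    },
    join = {
      need(1L)
      exec_join(state, thread, ops[[1L]])
    },
    merge = {
      need(1L)
      state$tokens[[length(state$tokens) + 1L]] <- ops[[1L]]
      list(status = "ok")
    },
    fire = {
      need(1L)
      spawn_if_needed(state, ops[[1L]], fiber = thread$fiber)
      list(status = "ok")
    },
    inc_weight = {
      need(2L)
      exec_adjust(state, thread, ops[[1L]], ops[[2L]], state$config$delta_ltp)
      list(status = "ok")
    },
    dec_weight = {
      need(2L)
      exec_adjust(state, thread, ops[[1L]], ops[[2L]], state$config$delta_ltd)
      list(status = "ok")
    },
    push = {
      need(1L)
      stm_push(state$stm, ops[[1L]])
      list(status = "ok")
    },
    pull = {
      need(1L)
      s <- stm_pull(state$stm, ops[[1L]])
      if (is.null(s)) list(status = "block") else list(status = "ok", bind = s)
    },
    store = {
      need(1L)
      ltm_store(state$ltm, ops[[1L]])
      list(status = "ok")
    },
    retrieve = {
      need(1L)
      subs <- ltm_retrieve(state$ltm, ops[[1L]])
      if (length(subs) == 0L) {
        list(status = "block")
      } else {
        list(status = "ok", bind = subs[[1L]])
      }
    },
    choose = {
      need(2L)
      exec_choose(state, thread, ops)
    },
    act = {
      need(1L)
      record_trace(state, thread, "effector_action", ops[[1L]])
      list(status = "ok")
    },
    emit = {
      need(1L)
      record_trace(state, thread, "internal_stimulus", ops[[1L]])
      if (length(ops) > 1L) {
        for (r in ops[-1L]) exec_send(state, thread, r, ops[[1L]])
      }
      list(status = "ok")
    },
    stop("unknown opcode ", sQuote(op), " in thread ", term_format(thread$id))
  )
}

## --- stepping and scheduling ---------------------------------------------

budget_error <- function(state) {
  stop(structure(class = c("fibervm_budget_error", "error", "condition"),
                 list(message = paste0("step budget (",
                                       state$config$max_steps_per_cycle,
                                       ") exhausted in presentation ",
                                       state$presentation),
                      call = NULL,
                      trace = vm_trace_df(state))))
}

#' Attempt one instruction step of a thread
#'
#' Whenever an instruction succeeds the thread clock advances by one and the
#' next instruction will be deduced; whenever it blocks it will be executed
#' again on a later round; when no implication matches the thread is done.
#'
#' @param state machine state.
#' @param thread a live thread.
#' @return one of `"advanced"`, `"retry"`, `"finished"`.
#' @export
step_thread <- function(state, thread) {
  if (thread$status != "active") stop("step_thread: thread is not active")
  state$steps_this_cycle <- state$steps_this_cycle + 1L
  if (state$steps_this_cycle > state$config$max_steps_per_cycle) {
    budget_error(state)
  }
  ## a blocked instruction is executed again until it succeeds: the
  ## deduction is stable while the clock (and hence the identity) is
  ## unchanged, so it is cached across retries
  if (!is.null(thread$cached_clock) && thread$cached_clock == thread$clock) {
    instr <- thread$cached_instr
  } else {
    instr <- deduce_instruction(thread, state$model, state)
    thread$cached_instr <- instr
    thread$cached_clock <- thread$clock
  }
  if (is.null(instr)) {
    thread$status <- "done"
    return("finished")
  }
  res <- exec_instruction(state, thread, instr)
  if (res$status == "ok") {
    if (!is.null(res$bind)) thread$id <- apply_subst(thread$id, res$bind)
    thread$clock <- thread$clock + 1L
    "advanced"
  } else {
    "retry"
  }
}

#' Run one scheduler round
#'
#' Cooperative round-robin: every thread active at the start of the round
#' attempts exactly one instruction, in deterministic order (fiber
#' activation order, then spawn order).  Threads fired during the round join
#' the next one.
#'
#' @param state machine state.
#' @return integer count of threads whose step advanced.
#' @export
schedule_round <- function(state) {
  roster <- Filter(function(th) th$status == "active", state$threads)
  if (length(roster) == 0L) return(0L)
  ord <- order(vapply(roster, function(th) th$fiber, integer(1L)),
               vapply(roster, function(th) th$spawn_id, integer(1L)))
  advanced <- 0L
  for (th in roster[ord]) {
    if (th$status != "active") next
    if (step_thread(state, th) == "advanced") advanced <- advanced + 1L
  }
  advanced
}

act_until_quiescent <- function(state) {
  repeat {
    if (schedule_round(state) == 0L) break
  }
}

#' Run one sense-act-reflect presentation cycle
#'
#' SENSE spawns one sensor thread per input element (each in its own fiber,
#' in element order, so stream sequence numbers restart at 1 every cycle);
#' ACT repeats scheduler rounds until quiescence (a full round with no
#' advancing thread); if the configuration carries a feedback function its
#' requested feedback threads are then fired and the machine runs to
#' quiescence again; REFLECT is the per-cycle trace of synchronization
#' events (sensor captures, internal stimuli, effector actions).  Unconsumed
#' signals and merge tokens are cleared at cycle end and all threads die;
#' only weights, STM and LTM persist across cycles.
#'
#' @param state machine state.
#' @param input a sensor vector term such as
#'   `sensor(left([green]),right([red]),sample([red]))`; its arguments are
#'   matched against the model's declared sensor patterns.
#' @return list of trace records of this cycle, invisibly (the records are
#'   also appended to the state's trace).
#' @export
run_presentation_cycle <- function(state, input) {
  input <- term(input)
  state$presentation <- state$presentation + 1L
  state$threads <- list()
  state$signals <- list()
  state$tokens <- list()
  state$fiber_count <- 0L
  state$steps_this_cycle <- 0L
  trace_mark <- length(state$trace)

  for (elem in input$args) {
    for (p in state$model$sensors) {
      sfx <- fresh_suffix(state)
      pat <- term_rename(p, sfx)
      s <- unify(pat, vm_term("sense", list(elem)))
      if (!is.null(s)) {
        spawn_thread(state, apply_subst(pat, s), fiber = NULL)
        break
      }
    }
  }

  act_until_quiescent(state)

  if (!is.null(state$config$feedback_fn)) {
    cycle_trace <- state$trace[seq_len(length(state$trace) - trace_mark) + trace_mark]
    fb <- state$config$feedback_fn(state, cycle_trace, input)
    if (length(fb)) {
      for (ident in fb) spawn_thread(state, term(ident), fiber = NULL)
      act_until_quiescent(state)
    }
  }

  blocked <- sum(vapply(state$threads, function(th) th$status == "active",
                        logical(1L)))
  if (blocked > 0L || length(state$signals) > 0L || length(state$tokens) > 0L) {
    state$diagnostics[[length(state$diagnostics) + 1L]] <- paste0(
      "presentation ", state$presentation, ": quiescent with ", blocked,
      " blocked thread(s), ", length(state$signals), " pending signal(s), ",
      length(state$tokens), " pending token(s)")
  }
  state$n_cleared <- state$n_cleared + length(state$signals)
  state$stream_log[[state$presentation]] <- state$fiber_count
  state$signals <- list()
  state$tokens <- list()
  state$threads <- list()

  invisible(state$trace[seq_len(length(state$trace) - trace_mark) + trace_mark])
}

vm_trace_df <- function(state) {
  trace_records_df(state$trace)
}

trace_records_df <- function(records) {
  if (length(records) == 0L) {
    return(data.frame(presentation = integer(), stream_seq = integer(),
                      thread = character(), local_time = integer(),
                      event_kind = character(), event = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    presentation = vapply(records, `[[`, integer(1L), "presentation"),
    stream_seq = vapply(records, `[[`, integer(1L), "stream_seq"),
    thread = vapply(records, `[[`, character(1L), "thread"),
    local_time = vapply(records, `[[`, integer(1L), "local_time"),
    event_kind = vapply(records, `[[`, character(1L), "event_kind"),
    event = vapply(records, `[[`, character(1L), "event"),
    stringsAsFactors = FALSE)
}

#' Run a compiled model over an input sequence
#'
#' Folds [run_presentation_cycle()] over the inputs and returns the final
#' machine state together with the concatenated trace.  Two runs with
#' identical (model, inputs, config) produce identical traces.
#'
#' @param model a [compile_circuit()] result.
#' @param inputs list of sensor vector terms (or canonical strings).
#' @param config a [vm_config()].
#' @return list with elements `state` (the machine) and `trace` (a
#'   data.frame of trace records with an `n_presentations` attribute).
#' @export
vm_run <- function(model, inputs, config = vm_config()) {
  state <- new_machine(model, config)
  for (input in inputs) run_presentation_cycle(state, input)
  trace <- vm_trace_df(state)
  attr(trace, "n_presentations") <- length(inputs)
  list(state = state, trace = trace)
}
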