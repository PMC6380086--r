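# Brute-force reference interpreter, written independently of the machine
# implementation: threads are plain lists mutated by index, implications are
# re-scanned linearly on every step, the signal queue and token pool are
# re-filtered on every attempt.  It shares only the term primitives
# (term/unify/apply_subst) with the package and applies the same scheduling
# policy: one instruction attempt per active thread per round, ordered by
# (fiber activation order, spawn order), quiescence when a full round
# advances nothing.  Supports the core opcodes used by the small circuits it
# is run against.

oracle_run <- function(model, inputs, threshold = 0L) {
  weights <- lapply(model$weights, function(w) {
    list(p = w$p, q = w$q, w = w$w)
  })
  vc <- 0L
  fresh <- function() {
    vc <<- vc + 1L
    paste0("orc", vc)
  }
  w_find <- function(p, q) {
    for (i in seq_along(weights)) {
      e <- weights[[i]]
      if (!is.null(unify(fibervm:::term_rename(e$p, fresh()), p)) &&
          !is.null(unify(fibervm:::term_rename(e$q, fresh()), q))) {
        return(i)
      }
    }
    stop("oracle: undeclared pathway ", term_format(p), " -> ", term_format(q))
  }
  trace <- list()

  for (pres in seq_along(inputs)) {
    threads <- list()
    signals <- list()
    tokens <- list()
    n_fiber <- 0L
    n_spawn <- 0L
    spawn <- function(id, fiber) {
      if (is.null(fiber)) {
        n_fiber <<- n_fiber + 1L
        fiber <- n_fiber
      }
      n_spawn <<- n_spawn + 1L
      threads[[length(threads) + 1L]] <<- list(id = id, clock = 1L,
                                               fiber = fiber,
                                               spawn = n_spawn, done = FALSE)
    }
    spawn_if_needed <- function(pat, fiber) {
      for (th in threads) {
        if (!th$done && !is.null(unify(pat, th$id))) return(invisible(NULL))
      }
      spawn(pat, fiber)
    }
    note <- function(th, kind, event) {
      trace[[length(trace) + 1L]] <<- list(
        presentation = pres, stream_seq = th$fiber,
        thread = term_format(th$id), local_time = th$clock,
        event_kind = kind, event = term_format(event))
    }

    input <- term(inputs[[pres]])
    for (elem in input$args) {
      for (p in model$sensors) {
        pat <- fibervm:::term_rename(p, fresh())
        u <- unify(pat, vm_term("sense", list(elem)))
        if (!is.null(u)) {
          spawn(apply_subst(pat, u), NULL)
          break
        }
      }
    }

    step_one <- function(i) {
      th <- threads[[i]]
      ## deduce: linear scan over all implications, declaration order
      instr <- NULL
      for (imp in model$implications) {
        if (imp$clock != th$clock) next
        sfx <- fresh()
        h <- fibervm:::term_rename(imp$head, sfx)
        s <- unify(h, th$id)
        if (is.null(s)) next
        instr <- list(op = imp$instr$opcode,
                      args = lapply(imp$instr$operands, function(o) {
                        apply_subst(fibervm:::term_rename(o, sfx), s)
                      }))
        break
      }
      if (is.null(instr)) {
        threads[[i]]$done <<- TRUE
        return("finished")
      }
      op <- instr$op
      a <- instr$args
      bind <- NULL
      ok <- TRUE
      if (op == "capture") {
        note(th, "sensor_capture", a[[1L]])
      } else if (op == "act") {
        note(th, "effector_action", a[[1L]])
      } else if (op %in% c("send", "emit")) {
        if (op == "emit") note(th, "internal_stimulus", a[[1L]])
        pairs <- if (op == "send") {
          list(list(r = a[[1L]], pl = a[[2L]]))
        } else {
          lapply(a[-1L], function(r) list(r = r, pl = a[[1L]]))
        }
        for (pr in pairs) {
          w_find(th$id, pr$r)  # wiring check
          spawn_if_needed(pr$r, th$fiber)
          signals[[length(signals) + 1L]] <<- list(from = th$id, to = pr$r,
                                                   pl = pr$pl)
        }
      } else if (op == "fire") {
        spawn_if_needed(a[[1L]], th$fiber)
      } else if (op == "merge") {
        tokens[[length(tokens) + 1L]] <<- a[[1L]]
      } else if (op == "join") {
        ok <- FALSE
        for (k in seq_along(tokens)) {
          s <- unify(a[[1L]], tokens[[k]])
          if (!is.null(s)) {
            tokens[[k]] <<- NULL
            bind <- s
            ok <- TRUE
            break
          }
        }
      } else if (op == "receive") {
        pats <- if (a[[1L]]$functor == "any") a[[1L]]$args else a[1L]
        ok <- FALSE
        for (k in seq_along(signals)) {
          sig <- signals[[k]]
          if (is.null(unify(sig$to, th$id))) next
          s <- NULL
          for (p in pats) {
            s <- unify(p, sig$from)
            if (!is.null(s)) break
          }
          if (is.null(s)) next
          s <- unify(a[[2L]], sig$pl, s)
          if (is.null(s)) next
          if (weights[[w_find(sig$from, th$id)]]$w <= threshold) next
          signals[[k]] <<- NULL
          bind <- s
          ok <- TRUE
          break
        }
      } else if (op %in% c("inc_weight", "dec_weight")) {
        k <- w_find(a[[1L]], a[[2L]])
        weights[[k]]$w <<- weights[[k]]$w + if (op == "inc_weight") 1L else -1L
      } else {
        stop("oracle: unsupported opcode ", op)
      }
      if (!ok) return("retry")
      if (!is.null(bind)) threads[[i]]$id <<- apply_subst(th$id, bind)
      threads[[i]]$clock <<- th$clock + 1L
      "advanced"
    }

    repeat {
      roster <- which(!vapply(threads, `[[`, logical(1L), "done"))
      if (length(roster) == 0L) break
      key <- order(vapply(threads[roster], `[[`, integer(1L), "fiber"),
                   vapply(threads[roster], `[[`, integer(1L), "spawn"))
      roster <- roster[key]
      adv <- 0L
      for (i in roster) {
        if (threads[[i]]$done) next
        if (step_one(i) == "advanced") adv <- adv + 1L
      }
      if (adv == 0L) break
    }
  }
  fibervm:::trace_records_df(trace)
}

# Canonical variable renaming for trace comparison: fresh-renaming suffixes
# are interpreter-private spellings of the same free variable.
normalized_trace <- function(df) {
  df$thread <- vapply(df$thread, fibervm:::normalize_term_string, "",
                      USE.NAMES = FALSE)
  df$event <- vapply(df$event, fibervm:::normalize_term_string, "",
                     USE.NAMES = FALSE)
  attributes(df) <- attributes(df)[c("names", "class", "row.names")]
  df
}

# Small parameterized circuit family for scheduler-oracle equivalence:
# every member has at most 3 declared nodes and instruction trees of depth
# at most 5.
oracle_family <- function() {
  specs <- list()
  ## two-node synapse, gate open or closed
  for (w1 in 0:1) {
    specs[[length(specs) + 1L]] <- list(
      spec = circuit_spec(
        name = paste0("syn", w1),
        nodes = c("sense(a)", "out(X)"),
        sensors = "sense(a)", effectors = "out(X)",
        connectors = list(list(kind = "synapse",
                               endpoints = c("sense(a)", "out(X)"))),
        weights = list(list(p = "sense(a)", q = "out(X)", w = w1))),
      input = "sensor(a)")
  }
  ## three-node relay chain, each gate open or closed
  for (w1 in 0:1) for (w2 in 0:1) {
    specs[[length(specs) + 1L]] <- list(
      spec = circuit_spec(
        name = paste0("chain", w1, w2),
        nodes = c("sense(a)", "mid(X)", "out(Y)"),
        sensors = "sense(a)", effectors = "out(Y)",
        connectors = list(
          list(kind = "synapse", endpoints = c("sense(a)", "mid(X)")),
          list(kind = "synapse", endpoints = c("mid(X)", "out(Y)"))),
        weights = list(list(p = "sense(a)", q = "mid(X)", w = w1),
                       list(p = "mid(X)", q = "out(Y)", w = w2))),
      input = "sensor(a)")
  }
  ## coincidence modulation (the ltp microcircuit), closed pathway w in 0:1
  for (w1 in 0:1) for (both in c(TRUE, FALSE)) {
    specs[[length(specs) + 1L]] <- list(
      spec = circuit_spec(
        name = paste0("mod", w1, both),
        nodes = c("sense(a)", "sense(b)", "out(X)"),
        sensors = c("sense(a)", "sense(b)"), effectors = "out(X)",
        connectors = list(
          list(kind = "synapse", endpoints = c("sense(b)", "out(X)")),
          list(kind = "modulation_up",
               endpoints = c("sense(a)", "sense(b)", "out(X)"))),
        weights = list(list(p = "sense(b)", q = "out(X)", w = w1))),
      input = if (both) "sensor(b,a)" else "sensor(b)")
  }
  ## diverging split behind an emitting relay
  specs[[length(specs) + 1L]] <- list(
    spec = circuit_spec(
      name = "splitfan",
      nodes = c("sense(a)", "lft(X)", "rgt(X)"),
      sensors = "sense(a)", effectors = c("lft(X)", "rgt(X)"),
      connectors = list(
        list(kind = "split", endpoints = c("sense(a)", "lft(X)", "rgt(X)"))),
      weights = list(list(p = "sense(a)", q = "lft(X)", w = 1L),
                     list(p = "sense(a)", q = "rgt(X)", w = 1L))),
    input = "sensor(a)")
  specs
}
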