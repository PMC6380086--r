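## Circuit description language and its compiler.  A circuit is a wiring
## diagram: nodes (thread identity patterns), protocol connectors between
## them, and declared initial weights.  Compilation lowers connectors to
## virtual-code implications mapping (thread identity, local time) to an
## instruction; a node may instead carry hand-written `rules` for behavior
## (deduction-based branching, internal-stimulus layers) that the closed
## connector vocabulary cannot express.

CONNECTOR_KINDS <- c("synapse", "modulation_up", "modulation_down",
                     "conjunction", "split", "choice")

#' Construct a circuit specification
#'
#' @param name circuit name.
#' @param nodes character vector of thread identity patterns in canonical
#'   term syntax (variables upper-case).
#' @param sensors,effectors subsets of `nodes` acting as sensor and effector
#'   threads.
#' @param connectors list of `list(kind=, endpoints=)` where `kind` is one
#'   of synapse (binary), modulation_up / modulation_down (ternary:
#'   modulator, source, target), conjunction, split, choice (n-ary; for
#'   choice the receiver is the last endpoint) and `endpoints` is a
#'   character vector of node patterns.
#' @param weights list of `list(p=, q=, w=)` initial pathway weights.
#' @param rules list of `list(thread=, clock=, instr=)` hand-written
#'   implications; a node whose functor appears here owns its full
#'   instruction tree and receives no template-generated instructions.
#' @param stm_capacity,stm_initial short-term cache configuration.
#' @param ltm_initial initial long-term memory facts.
#' @return A `circuit_spec` object.
#' @export
circuit_spec <- function(name, nodes, sensors = character(),
                         effectors = character(), connectors = list(),
                         weights = list(), rules = list(),
                         stm_capacity = 1L, stm_initial = character(),
                         ltm_initial = character()) {
  structure(list(name = name, nodes = as.character(nodes),
                 sensors = as.character(sensors),
                 effectors = as.character(effectors),
                 connectors = connectors, weights = weights, rules = rules,
                 stm_capacity = as.integer(stm_capacity),
                 stm_initial = as.character(stm_initial),
                 ltm_initial = as.character(ltm_initial)),
            class = "circuit_spec")
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat("<circuit_spec>", x$name, "-", length(x$nodes), "nodes,",
      length(x$connectors), "connectors,", length(x$rules), "rules\n")
  invisible(x)
}

endpoint_declared <- function(spec, ep) {
  ep <- term(ep)
  for (n in spec$nodes) {
    if (!is.null(unify(term_rename(term(n), "nd"), term_rename(ep, "ep")))) {
      return(TRUE)
    }
  }
  FALSE
}

#' Validate a circuit specification
#'
#' @param spec a [circuit_spec()].
#' @return character vector of diagnostics; empty iff [compile_circuit()]
#'   would succeed.
#' @export
validate_circuit <- function(spec) {
  diags <- character()
  say <- function(...) diags[[length(diags) + 1L]] <<- paste0(...)
  if (anyDuplicated(spec$nodes)) {
    say("duplicate node: ", spec$nodes[duplicated(spec$nodes)][1L])
  }
  for (n in c(spec$nodes, spec$sensors, spec$effectors)) {
    ok <- tryCatch({ term(n); TRUE }, error = function(e) FALSE)
    if (!ok) say("unparseable node pattern: ", n)
  }
  if (length(diags)) return(diags)
  arity_min <- c(synapse = 2L, modulation_up = 3L, modulation_down = 3L,
                 conjunction = 2L, split = 2L, choice = 2L)
  arity_max <- c(synapse = 2L, modulation_up = 3L, modulation_down = 3L,
                 conjunction = Inf, split = Inf, choice = Inf)
  for (i in seq_along(spec$connectors)) {
    cn <- spec$connectors[[i]]
    if (!cn$kind %in% CONNECTOR_KINDS) {
      say("connector ", i, ": unknown kind ", sQuote(cn$kind))
      next
    }
    n_ep <- length(cn$endpoints)
    if (n_ep < arity_min[[cn$kind]] || n_ep > arity_max[[cn$kind]]) {
      say("connector ", i, " (", cn$kind, "): bad arity ", n_ep)
    }
    for (ep in cn$endpoints) {
      if (!endpoint_declared(spec, ep)) {
        say("connector ", i, " (", cn$kind, "): dangling endpoint ", ep)
      }
    }
  }
  for (i in seq_along(spec$rules)) {
    r <- spec$rules[[i]]
    if (!endpoint_declared(spec, r$thread)) {
      say("rule ", i, ": head ", r$thread, " matches no declared node")
    }
    it <- tryCatch(term(r$instr), error = function(e) NULL)
    if (is.null(it)) {
      say("rule ", i, ": unparseable instruction ", r$instr)
    } else if (!it$functor %in% VM_OPCODES) {
      say("rule ", i, ": unknown opcode ", sQuote(it$functor))
    }
    if (as.integer(r$clock) < 1L) say("rule ", i, ": clock must be >= 1")
  }
  for (i in seq_along(spec$weights)) {
    w <- spec$weights[[i]]
    if (!endpoint_declared(spec, w$p) || !endpoint_declared(spec, w$q)) {
      say("weight ", i, ": pathway ", w$p, " -> ", w$q,
          " references an undeclared node")
    }
  }
  diags
}

#' Compile a circuit to a model
#'
#' Lowers each connector to instructions by kind: sensors get a capture
#' followed by one send per outgoing connector; synapse targets get
#' weight-gated receives (merged into a single first-signal-wins receive
#' when a choice connector covers them); modulation connectors give the
#' modulator a fire of an ltp/ltd coincidence-detector thread, the source a
#' merge token, and add the detector's join + inc/dec_weight tree; split
#' fans one send out to several targets; conjunction pairs a join and a
#' merge between its endpoints.  Declaration order of connectors fixes
#' instruction order, and hand-written `rules` are appended in their own
#' order, so compilation is deterministic.
#'
#' @param spec a [circuit_spec()].
#' @return A `compiled_model`.
#' @export
compile_circuit <- function(spec) {
  diags <- validate_circuit(spec)
  if (length(diags)) {
    stop("invalid circuit ", sQuote(spec$name), ":\n  ",
         paste(diags, collapse = "\n  "))
  }
  imps <- list()
  add <- function(head, clock, opcode, operands) {
    imps[[length(imps) + 1L]] <<- list(head = term(head),
                                       clock = as.integer(clock),
                                       instr = list(opcode = opcode,
                                                    operands = operands))
  }
  same <- function(a, b) term_format(term(a)) == term_format(term(b))
  custom_functors <- unique(vapply(spec$rules,
                                   function(r) term(r$thread)$functor, ""))
  mod_kinds <- c(modulation_up = "ltp", modulation_down = "ltd")

  for (nstr in spec$nodes) {
    node <- term(nstr)
    if (node$functor %in% custom_functors) next
    clock <- 1L
    put <- function(opcode, operands) {
      add(node, clock, opcode, operands)
      clock <<- clock + 1L
    }
    is_sensor <- any(vapply(spec$sensors, same, logical(1L), b = nstr))
    payload <- if (length(node$args) == 1L) node$args[[1L]] else node
    if (is_sensor) put("capture", list(payload))

    ## incoming: choice connectors first (first-signal-wins receive), then
    ## plain synapse receives not covered by a choice
    bind <- if (length(node$args) == 1L) node$args[[1L]] else vm_var("Payload")
    covered <- character()
    for (cn in spec$connectors) {
      if (cn$kind != "choice") next
      recv <- cn$endpoints[[length(cn$endpoints)]]
      if (!same(recv, nstr)) next
      senders <- lapply(cn$endpoints[-length(cn$endpoints)], term)
      covered <- c(covered, vapply(senders, term_format, ""))
      put("receive", list(vm_term("any", senders), bind))
    }
    for (cn in spec$connectors) {
      if (cn$kind != "synapse" || !same(cn$endpoints[[2L]], nstr)) next
      if (term_format(term(cn$endpoints[[1L]])) %in% covered) next
      put("receive", list(term(cn$endpoints[[1L]]), bind))
    }
    ## conjunction: first endpoint joins, later endpoints merge the token
    for (cn in spec$connectors) {
      if (cn$kind != "conjunction") next
      tok <- vm_term("conj_tok", lapply(cn$endpoints, term))
      if (same(cn$endpoints[[1L]], nstr)) {
        put("join", list(tok))
      } else if (any(vapply(cn$endpoints[-1L], same, logical(1L), b = nstr))) {
        put("merge", list(tok))
      }
    }
    ## modulation roles
    for (cn in spec$connectors) {
      if (!cn$kind %in% names(mod_kinds)) next
      fn <- mod_kinds[[cn$kind]]
      src <- term(cn$endpoints[[2L]])
      tgt <- term(cn$endpoints[[3L]])
      if (same(cn$endpoints[[1L]], nstr)) {
        put("fire", list(vm_term(fn, list(src, tgt))))
      }
      if (same(cn$endpoints[[2L]], nstr)) {
        put("merge", list(vm_term(paste0(fn, "_tok"), list(src, tgt))))
      }
    }
    ## outgoing sends
    for (cn in spec$connectors) {
      if (cn$kind == "synapse" && same(cn$endpoints[[1L]], nstr)) {
        put("send", list(term(cn$endpoints[[2L]]), payload))
      }
      if (cn$kind == "split" && same(cn$endpoints[[1L]], nstr)) {
        for (tg in cn$endpoints[-1L]) put("send", list(term(tg), payload))
      }
    }
    if (any(vapply(spec$effectors, same, logical(1L), b = nstr))) {
      put("act", list(node))
    }
  }

  ## coincidence-detector threads contributed by modulation connectors
  for (cn in spec$connectors) {
    if (!cn$kind %in% names(mod_kinds)) next
    fn <- mod_kinds[[cn$kind]]
    src <- term(cn$endpoints[[2L]])
    tgt <- term(cn$endpoints[[3L]])
    ident <- vm_term(fn, list(src, tgt))
    add(ident, 1L, "join", list(vm_term(paste0(fn, "_tok"), list(src, tgt))))
    add(ident, 2L, if (fn == "ltp") "inc_weight" else "dec_weight",
        list(src, tgt))
  }

  for (r in spec$rules) {
    it <- term(r$instr)
    add(term(r$thread), as.integer(r$clock), it$functor, it$args)
  }

  index <- list()
  for (i in seq_along(imps)) {
    key <- paste0(imps[[i]]$head$functor, "/", imps[[i]]$clock)
    index[[key]] <- c(index[[key]], i)
  }

  structure(list(name = spec$name,
                 implications = imps,
                 index = index,
                 weights = lapply(spec$weights, function(w) {
                   list(p = term(w$p), q = term(w$q), w = as.integer(w$w))
                 }),
                 sensors = lapply(spec$sensors, term),
                 effectors = lapply(spec$effectors, term),
                 stm_capacity = spec$stm_capacity,
                 stm_initial = as.list(spec$stm_initial),
                 ltm_initial = as.list(spec$ltm_initial)),
            class = "compiled_model")
}

#' @export
print.compiled_model <- function(x, ...) {
  cat("<compiled_model>", x$name, "-", length(x$implications),
      "implications,", length(x$weights), "pathways\n")
  invisible(x)
}

#' Canonical text form of a compiled model's implications
#'
#' One line per implication, used for round-trip and determinism checks.
#'
#' @param model a compiled model.
#' @return character vector.
#' @export
model_listing <- function(model) {
  vapply(model$implications, function(im) {
    ops <- paste(vapply(im$instr$operands, term_format, ""), collapse = ",")
    sprintf("%s @ %d -> %s(%s)", term_format(im$head), im$clock,
            im$instr$opcode, ops)
  }, "")
}

#' Write a circuit specification to YAML
#'
#' @param spec a [circuit_spec()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_circuit <- function(spec, path) {
  yaml::write_yaml(list(
    name = spec$name,
    nodes = as.list(spec$nodes),
    sensors = as.list(spec$sensors),
    effectors = as.list(spec$effectors),
    connectors = lapply(spec$connectors, function(cn) {
      list(kind = cn$kind, endpoints = as.list(cn$endpoints))
    }),
    weights = lapply(spec$weights, function(w) {
      list(p = w$p, q = w$q, w = as.integer(w$w))
    }),
    rules = lapply(spec$rules, function(r) {
      list(thread = r$thread, clock = as.integer(r$clock), instr = r$instr)
    }),
    stm_capacity = spec$stm_capacity,
    stm_initial = as.list(spec$stm_initial),
    ltm_initial = as.list(spec$ltm_initial)), path)
  invisible(path)
}

#' Read a circuit specification from YAML
#'
#' @param path file written by [write_circuit()] (or hand-edited).
#' @return A [circuit_spec()].
#' @export
read_circuit <- function(path) {
  y <- yaml::read_yaml(path)
  circuit_spec(name = y$name,
               nodes = unlist(y$nodes),
               sensors = if (length(y$sensors)) unlist(y$sensors) else character(),
               effectors = if (length(y$effectors)) unlist(y$effectors) else character(),
               connectors = lapply(y$connectors, function(cn) {
                 list(kind = cn$kind, endpoints = unlist(cn$endpoints))
               }),
               weights = y$weights,
               rules = y$rules,
               stm_capacity = y$stm_capacity,
               stm_initial = if (length(y$stm_initial)) unlist(y$stm_initial) else character(),
               ltm_initial = if (length(y$ltm_initial)) unlist(y$ltm_initial) else character())
}
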