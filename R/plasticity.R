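#' Weight tables
#'
#' The plastic state of a circuit: integer weights attached to declared
#' (sender pattern, receiver pattern) pathways.  A receive proceeds only if
#' the weight on its pathway stands strictly above the table's threshold, so
#' with the defaults a weight of 1 is an open pathway and 0 a closed one.
#' Lookup unifies the concrete (sender, receiver) pair against the declared
#' patterns; circuit builders guarantee that exactly one entry matches any
#' pathway actually used.
#'
#' @param entries list of `list(p=, q=, w=)` pathway declarations (terms or
#'   canonical strings).
#' @param threshold integer gate threshold (default 0).
#' @param w_min,w_max integer clamp bounds for plasticity.
#' @return A `weight_table` environment.
#' @export
weight_table <- function(entries = list(), threshold = 0L,
                         w_min = -5L, w_max = 5L) {
  wt <- new.env(parent = emptyenv())
  ## entry patterns are standardized apart once, at construction, with a
  ## reserved suffix that machine-generated renamings (numeric) never use
  wt$p <- lapply(seq_along(entries), function(i) {
    term_rename(term(entries[[i]]$p), paste0("w", i))
  })
  wt$q <- lapply(seq_along(entries), function(i) {
    term_rename(term(entries[[i]]$q), paste0("w", i))
  })
  wt$keys <- vapply(entries, function(e) {
    paste0(term_format(term(e$p)), " -> ", term_format(term(e$q)))
  }, "")
  wt$pf <- vapply(wt$p, function(t) t$functor, "")
  wt$qf <- vapply(wt$q, function(t) t$functor, "")
  wt$w <- vapply(entries, function(e) as.integer(e$w), integer(1L))
  wt$threshold <- as.integer(threshold)
  wt$w_min <- as.integer(w_min)
  wt$w_max <- as.integer(w_max)
  class(wt) <- "weight_table"
  wt
}

weight_entry_index <- function(wt, p, q) {
  p <- term(p)
  q <- term(q)
  hits <- integer()
  for (i in which(wt$pf == p$functor & wt$qf == q$functor)) {
    if (is.null(unify(wt$p[[i]], p))) next
    if (is.null(unify(wt$q[[i]], q))) next
    hits[[length(hits) + 1L]] <- i
  }
  hits
}

#' Look up the weight on a pathway
#'
#' @param wt a [weight_table()].
#' @param p,q sender and receiver identities (terms or strings).
#' @return integer weight.
#' @export
weight_lookup <- function(wt, p, q) {
  i <- weight_entry_index(wt, p, q)
  if (length(i) == 0L) {
    stop("undeclared pathway: ", term_format(term(p)), " -> ", term_format(term(q)))
  }
  wt$w[i[1L]]
}

weight_declared <- function(wt, p, q) length(weight_entry_index(wt, p, q)) > 0L

#' Adjust a pathway weight (LTP/LTD)
#'
#' Long-term potentiation adds +1, depression -1; results are clamped to the
#' table's `[w_min, w_max]` range.  The unique declared entry whose patterns
#' unify with `(p, q)` is mutated, so a pattern-level declaration learns a
#' relation that generalizes across instantiations while ground declarations
#' learn configuration-specific links.
#'
#' @inheritParams weight_lookup
#' @param delta integer increment (ltp +1, ltd -1).
#' @return the new integer weight.
#' @export
adjust_weight <- function(wt, p, q, delta) {
  i <- weight_entry_index(wt, p, q)
  if (length(i) == 0L) {
    stop("undeclared pathway: ", term_format(term(p)), " -> ", term_format(term(q)))
  }
  i <- i[1L]
  wt$w[i] <- max(wt$w_min, min(wt$w_max, wt$w[i] + as.integer(delta)))
  wt$w[i]
}

#' Serialize a weight table
#'
#' Produces the checkpoint form: a JSON map from the canonical pathway
#' string `"P -> Q"` to the integer weight.
#'
#' @param wt a [weight_table()].
#' @param path optional file; when given the JSON is written there.
#' @return named integer vector (invisibly when writing to a file).
#' @export
weight_dump <- function(wt, path = NULL) {
  out <- stats::setNames(as.integer(wt$w), wt$keys)
  if (!is.null(path)) {
    jsonlite::write_json(as.list(out), path, auto_unbox = TRUE)
    return(invisible(out))
  }
  out
}

#' Restore weights from a checkpoint
#'
#' @param wt a [weight_table()] with the same declared pathways.
#' @param path JSON file written by [weight_dump()].
#' @return the table, invisibly.
#' @export
weight_load <- function(wt, path) {
  vals <- jsonlite::read_json(path)
  for (k in names(vals)) {
    i <- match(k, wt$keys)
    if (is.na(i)) stop("weight_load: unknown pathway ", sQuote(k))
    wt$w[i] <- as.integer(vals[[k]])
  }
  invisible(wt)
}

#' @export
print.weight_table <- function(x, ...) {
  d <- weight_dump(x)
  cat("<weight_table> threshold", x$threshold,
      "clamp [", x$w_min, ",", x$w_max, "]\n")
  for (i in seq_along(d)) cat(sprintf("  %-55s %d\n", names(d)[i], d[i]))
  invisible(x)
}

## --- short-term cache (STM) ----------------------------------------------

#' Short-term cache memory
#'
#' A bounded FIFO of terms modeling a short-term memory; pushing beyond
#' capacity evicts the oldest item.  The default capacity of one slot is the
#' "remember one's last choice" memory used by the win/stay-lose/shift
#' circuit.
#'
#' @param capacity positive integer number of slots.
#' @param initial list of terms (or strings) preloaded into the cache.
#' @return An `stm_cache` environment.
#' @export
stm_cache <- function(capacity = 1L, initial = list()) {
  stopifnot(capacity >= 1L)
  cache <- new.env(parent = emptyenv())
  cache$capacity <- as.integer(capacity)
  cache$slots <- lapply(initial, term)
  if (length(cache$slots) > cache$capacity) {
    cache$slots <- utils::tail(cache$slots, cache$capacity)
  }
  class(cache) <- "stm_cache"
  cache
}

#' Push an item into the short-term cache
#'
#' @param cache an [stm_cache()].
#' @param item term (or canonical string).
#' @return the cache, invisibly.
#' @export
stm_push <- function(cache, item) {
  cache$slots[[length(cache$slots) + 1L]] <- term(item)
  if (length(cache$slots) > cache$capacity) {
    cache$slots <- cache$slots[-1L]
  }
  invisible(cache)
}

#' Read the short-term cache
#'
#' Unifies `pattern` against the cached items, most recent first; the read
#' is non-destructive.
#'
#' @param cache an [stm_cache()].
#' @param pattern term pattern.
#' @return a substitution, or `NULL` when nothing matches.
#' @export
stm_pull <- function(cache, pattern) {
  pattern <- term(pattern)
  for (i in rev(seq_along(cache$slots))) {
    s <- unify(pattern, cache$slots[[i]])
    if (!is.null(s)) return(s)
  }
  NULL
}

## --- associative long-term memory (LTM) ----------------------------------

#' Associative long-term memory
#'
#' An append-only store of ground facts with unification-based retrieval;
#' retrieval never mutates the store.
#'
#' @param initial list of terms (or strings) preloaded as facts.
#' @return An `ltm_store` environment.
#' @export
ltm_store_new <- function(initial = list()) {
  store <- new.env(parent = emptyenv())
  store$facts <- lapply(initial, term)
  class(store) <- "ltm_store"
  store
}

#' Store a fact in long-term memory
#'
#' Duplicates are allowed; storage never affects synaptic weights.
#'
#' @param store an [ltm_store_new()].
#' @param fact term (or canonical string).
#' @return the store, invisibly.
#' @export
ltm_store <- function(store, fact) {
  store$facts[[length(store$facts) + 1L]] <- term(fact)
  invisible(store)
}

#' Retrieve facts by cue
#'
#' @param store an [ltm_store_new()].
#' @param cue term pattern.
#' @return list of substitutions for every matching fact, most recent first
#'   (empty list when none match).
#' @export
ltm_retrieve <- function(store, cue) {
  cue <- term(cue)
  out <- list()
  for (i in rev(seq_along(store$facts))) {
    s <- unify(cue, store$facts[[i]])
    if (!is.null(s)) out[[length(out) + 1L]] <- s
  }
  out
}
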