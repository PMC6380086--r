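## Execution-trace analysis: per-cycle internal-stimulus signatures,
## transient/persistent segmentation and the reactive vs rule-based
## behavior classification, plus the JSON Lines trace format.

#' Write a trace as JSON Lines
#'
#' One JSON object per trace record with keys presentation, stream_seq,
#' thread, local_time, event_kind, event; terms are in canonical syntax.
#'
#' @param trace trace data.frame from [vm_run()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
trace_write_jsonl <- function(trace, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  if (nrow(trace)) {
    for (i in seq_len(nrow(trace))) {
      writeLines(jsonlite::toJSON(as.list(trace[i, , drop = FALSE]),
                                  auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Read a JSON Lines trace
#'
#' @param path file written by [trace_write_jsonl()].
#' @param n_presentations optional presentation count (recorded as an
#'   attribute; defaults to the largest presentation index present).
#' @return trace data.frame.
#' @export
trace_read_jsonl <- function(path, n_presentations = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  records <- lapply(lines, function(l) {
    r <- jsonlite::fromJSON(l)
    list(presentation = as.integer(r$presentation),
         stream_seq = as.integer(r$stream_seq),
         thread = r$thread, local_time = as.integer(r$local_time),
         event_kind = r$event_kind, event = r$event)
  })
  trace <- trace_records_df(records)
  attr(trace, "n_presentations") <- if (is.null(n_presentations)) {
    if (nrow(trace)) max(trace$presentation) else 0L
  } else {
    as.integer(n_presentations)
  }
  trace
}

## canonical variable renaming (V1, V2, ... in order of appearance) so that
## signatures compare by structure, not by accidental variable names
normalize_term_string <- function(s) {
  t <- term(s)
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$map <- list()
  walk <- function(x) {
    if (is_var(x)) {
      if (is.null(env$map[[x$name]])) {
        env$n <- env$n + 1L
        env$map[[x$name]] <- paste0("V", env$n)
      }
      return(vm_var(env$map[[x$name]]))
    }
    if (length(x$args)) x$args <- lapply(x$args, walk)
    x
  }
  term_format(walk(t))
}

#' Per-cycle internal-stimulus signatures
#'
#' The signature of a presentation cycle is the ordered sequence of
#' internal stimuli (fetch, excite, inhibit, ...) emitted during it;
#' cycles without internal stimuli have an empty signature and reflect
#' purely reactive sensor-to-effector behavior.
#'
#' @param trace trace data.frame, sorted by presentation (as produced by
#'   [vm_run()]).
#' @param n_presentations number of cycles covered by the trace; defaults
#'   to the trace's `n_presentations` attribute.
#' @return list of `cycle_signature` objects
#'   (`list(presentation=, stimuli=character())`).
#' @export
cycle_signatures <- function(trace, n_presentations = NULL) {
  if (is.unsorted(trace$presentation)) {
    stop("trace is not sorted by presentation")
  }
  if (is.null(n_presentations)) {
    n_presentations <- attr(trace, "n_presentations")
  }
  if (is.null(n_presentations)) {
    n_presentations <- if (nrow(trace)) max(trace$presentation) else 0L
  }
  lapply(seq_len(n_presentations), function(i) {
    ev <- trace$event[trace$presentation == i &
                        trace$event_kind == "internal_stimulus"]
    structure(list(presentation = i,
                   stimuli = vapply(ev, normalize_term_string, "",
                                    USE.NAMES = FALSE)),
              class = "cycle_signature")
  })
}

signature_key <- function(sig) paste(sig$stimuli, collapse = " ; ")

#' Segment a run into transient and persistent parts
#'
#' A run has converged when its final cycle signature repeats unchanged
#' for at least `stability_window` consecutive cycles up to the end; the
#' transient part is everything before the stable suffix.
#'
#' @param signatures list from [cycle_signatures()].
#' @param stability_window minimum length of the stable suffix (default 5).
#' @return A `vm_segmentation`: list with `converged`, `transient_end`
#'   (index of the last cycle whose signature differs from the stable one;
#'   0 when all cycles share it), `stable_signature` (character vector of
#'   stimuli, empty for reactive behavior) and `n_cycles`.
#' @export
segment_trace <- function(signatures, stability_window = 5L) {
  n <- length(signatures)
  if (n == 0L) stop("segment_trace: no signatures")
  keys <- vapply(signatures, signature_key, "")
  final <- keys[n]
  transient_end <- 0L
  for (i in rev(seq_len(n))) {
    if (keys[i] != final) {
      transient_end <- i
      break
    }
  }
  stable_len <- n - transient_end
  converged <- stable_len >= stability_window
  structure(list(converged = converged,
                 transient_end = if (converged) transient_end else NA_integer_,
                 stable_signature = if (converged) {
                   signatures[[n]]$stimuli
                 } else {
                   character()
                 },
                 n_cycles = n,
                 stability_window = as.integer(stability_window)),
            class = "vm_segmentation")
}

#' @export
print.vm_segmentation <- function(x, ...) {
  if (!x$converged) {
    cat("<segmentation> not converged over", x$n_cycles, "cycles\n")
    return(invisible(x))
  }
  cat("<segmentation>", x$n_cycles, "cycles; transient 1..", x$transient_end,
      "; stable signature: ",
      if (length(x$stable_signature)) {
        paste(x$stable_signature, collapse = ", ")
      } else {
        "(empty)"
      }, "\n")
  invisible(x)
}

#' Classify trace behavior
#'
#' An empty stable signature (no internal stimuli per cycle) is reactive
#' behavior, a non-empty recurrent one is rule-based behavior, and a run
#' without a stable suffix is not converged.
#'
#' @param seg a [segment_trace()] result.
#' @return `"reactive"`, `"rule_based"` or `"not_converged"`.
#' @export
classify_behavior <- function(seg) {
  stopifnot(inherits(seg, "vm_segmentation"))
  if (!seg$converged) return("not_converged")
  if (length(seg$stable_signature) == 0L) "reactive" else "rule_based"
}

#' Synchronization anchor of a cycle
#'
#' Each recurrent pattern reflects the synchronization of an internal
#' stimulus with its supporting stream: the anchor is the (thread, local
#' time, stream sequence) triple of the cycle's internal-stimulus record.
#'
#' @param trace trace data.frame.
#' @param presentation cycle index.
#' @param index which internal-stimulus record to anchor on when the cycle
#'   holds more than one (required in that case).
#' @return list `(thread, local_time, stream_seq, event)` or NULL when the
#'   cycle has no internal stimulus.
#' @export
sync_anchor <- function(trace, presentation, index = NULL) {
  if (!presentation %in% trace$presentation) {
    stop("presentation ", presentation, " not present in trace")
  }
  rec <- trace[trace$presentation == presentation &
                 trace$event_kind == "internal_stimulus", , drop = FALSE]
  if (nrow(rec) == 0L) return(NULL)
  if (nrow(rec) > 1L && is.null(index)) {
    stop("presentation ", presentation, " has ", nrow(rec),
         " internal stimuli; pass `index` to select an anchor")
  }
  i <- if (is.null(index)) 1L else as.integer(index)
  list(thread = rec$thread[i], local_time = rec$local_time[i],
       stream_seq = rec$stream_seq[i], event = rec$event[i])
}

#' Summary report for a trace
#'
#' @param trace trace data.frame.
#' @param stability_window see [segment_trace()].
#' @param path optional file; when given the report is written as JSON.
#' @return list with classification, transient length, stable signature and
#'   the sync anchor of the final cycle (if unique).
#' @export
trace_report <- function(trace, stability_window = 5L, path = NULL) {
  sigs <- cycle_signatures(trace)
  seg <- segment_trace(sigs, stability_window)
  cls <- classify_behavior(seg)
  anchor <- NULL
  if (cls == "rule_based" && length(seg$stable_signature) == 1L) {
    anchor <- sync_anchor(trace, seg$n_cycles)
  }
  rep <- list(classification = cls,
              n_cycles = seg$n_cycles,
              transient_end = seg$transient_end,
              stable_signature = as.list(seg$stable_signature),
              sync_anchor = anchor)
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, null = "null")
  }
  rep
}
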