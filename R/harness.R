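## Experiment harness: stimulus constructors, reward-feedback evaluation,
## orchestration of build -> compile -> run -> analyze, and the two demo
## replications of the configural and rule-learning trace experiments.

#' Build a non-matching-to-sample input vector
#'
#' @param left_color,right_color,sample_color colors drawn from `palette`.
#' @param palette allowed colors (default red/green).
#' @return the sensor vector term
#'   `sensor(left([L]),right([R]),sample([S]))`.
#' @examples
#' make_nmts_input("green", "red", "red")
#' @export
make_nmts_input <- function(left_color, right_color, sample_color,
                            palette = c("red", "green")) {
  cols <- c(left_color, right_color, sample_color)
  bad <- setdiff(cols, palette)
  if (length(bad)) {
    stop("color(s) outside palette (", paste(palette, collapse = ", "),
         "): ", paste(bad, collapse = ", "))
  }
  term(sprintf("sensor(left([%s]),right([%s]),sample([%s]))",
               left_color, right_color, sample_color))
}

#' Experiment configuration
#'
#' A fully serializable description of one simulation run; a run is
#' reproducible from the configuration (plus circuit files) alone.
#'
#' @param model_name one of the [build_model()] names.
#' @param n_presentations number of presentation cycles (default 40).
#' @param seed machine PRNG seed.
#' @param threshold,delta_ltp,delta_ltd,w_min,w_max,max_steps_per_cycle,stability_window
#'   see [vm_config()].
#' @param block_size presentations per block for reward-rate reporting.
#' @param palette NMTS color palette.
#' @param nmts_left,nmts_right,nmts_sample the fixed NMTS configuration
#'   presented on every cycle (defaults to the green/red/red vector of the
#'   trace experiments).
#' @param operant_correct which operant action is consistently rewarded.
#' @param wsls_reward_side rewarded side per trial for win/stay-lose/shift
#'   (a single side or a vector recycled over trials).
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(model_name, n_presentations = 40L, seed = 1L,
                              threshold = 0L, delta_ltp = 1L, delta_ltd = -1L,
                              w_min = -5L, w_max = 5L,
                              max_steps_per_cycle = 10000L,
                              stability_window = 5L, block_size = 10L,
                              palette = c("red", "green"),
                              nmts_left = "green", nmts_right = "red",
                              nmts_sample = "red",
                              operant_correct = "accept",
                              wsls_reward_side = "left") {
  model_name <- match.arg(model_name, MODEL_NAMES)
  structure(list(model_name = model_name,
                 n_presentations = as.integer(n_presentations),
                 seed = as.integer(seed), threshold = as.integer(threshold),
                 delta_ltp = as.integer(delta_ltp),
                 delta_ltd = as.integer(delta_ltd),
                 w_min = as.integer(w_min), w_max = as.integer(w_max),
                 max_steps_per_cycle = as.integer(max_steps_per_cycle),
                 stability_window = as.integer(stability_window),
                 block_size = as.integer(block_size), palette = palette,
                 nmts_left = nmts_left, nmts_right = nmts_right,
                 nmts_sample = nmts_sample,
                 operant_correct = operant_correct,
                 wsls_reward_side = wsls_reward_side),
            class = "experiment_config")
}

#' Write / read an experiment configuration
#'
#' @param config an [experiment_config()].
#' @param path YAML file.
#' @return `path` invisibly / the configuration.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(experiment_config, y)
}

term_arg_string <- function(s, i = 1L) term_format(term(s)$args[[i]])

## color of the chosen NMTS button, read off the input vector
nmts_choice_color <- function(input, side) {
  for (elem in input$args) {
    if (elem$functor == side) return(term_format(elem$args[[1L]]))
  }
  NA_character_
}

cycle_events <- function(cycle_trace, kind) {
  Filter(function(r) r$event_kind == kind, cycle_trace)
}

cycle_has_fetch <- function(cycle_trace) {
  any(vapply(cycle_events(cycle_trace, "internal_stimulus"),
             function(r) term(r$event)$functor == "fetch", logical(1L)))
}

log_reward <- function(state, action, rewarded) {
  state$reward_log[[state$presentation]] <- list(action = action,
                                                 rewarded = rewarded)
}

## Reward evaluation per model.  For the conditioning/NMTS models the
## excite/inhibit feedback threads are fired only in cycles that explored
## (emitted a fetch): once behavior runs through a learned route the reward
## no longer drives any internal broadcast, which is what leaves converged
## cycles free of feedback stimuli.  Win/stay-lose/shift instead refreshes
## its short-term memory on every trial.
make_feedback_fn <- function(config) {
  model_name <- config$model_name
  if (model_name %in% c("classical", "categorical_sort")) return(NULL)
  function(state, cycle_trace, input) {
    acts <- cycle_events(cycle_trace, "effector_action")
    if (length(acts) == 0L) {
      log_reward(state, NA_character_, FALSE)
      return(NULL)
    }
    action <- term(acts[[1L]]$event)
    if (model_name %in% c("configural_nmts", "rule_nmts")) {
      side <- term_format(action$args[[1L]])
      chosen <- nmts_choice_color(input, side)
      sample <- nmts_choice_color(input, "sample")
      rewarded <- !is.na(chosen) && chosen != sample
      log_reward(state, term_format(action), rewarded)
      if (!cycle_has_fetch(cycle_trace)) return(NULL)
      list(vm_term(if (rewarded) "reward" else "punish", list(action)))
    } else if (model_name == "operant") {
      rewarded <- action$functor == config$operant_correct
      log_reward(state, term_format(action), rewarded)
      if (!cycle_has_fetch(cycle_trace)) return(NULL)
      list(vm_term(if (rewarded) "reward" else "punish", list(action)))
    } else if (model_name == "win_stay_lose_shift") {
      side <- term_format(action$args[[1L]])
      sched <- rep_len(config$wsls_reward_side, state$presentation)
      rewarded <- side == sched[[state$presentation]]
      log_reward(state, term_format(action), rewarded)
      list(vm_term(if (rewarded) "reward" else "punish", list(action)))
    } else {
      NULL
    }
  }
}

default_inputs <- function(config) {
  n <- config$n_presentations
  switch(config$model_name,
    classical = c(rep(list(term("sensor(cs,us)")), max(0L, n - 1L)),
                  list(term("sensor(cs)"))),
    operant = rep(list(term("sensor(cue(key))")), n),
    configural_nmts = ,
    rule_nmts = rep(list(make_nmts_input(config$nmts_left, config$nmts_right,
                                         config$nmts_sample, config$palette)),
                    n),
    win_stay_lose_shift = rep(list(term("sensor(go)")), n),
    categorical_sort = {
      study <- list(term("sensor(study(item(i1),color(red)))"),
                    term("sensor(study(item(i2),color(green)))"),
                    term("sensor(assign(color(red),bin(b1)))"),
                    term("sensor(assign(color(green),bin(b2)))"))
      queries <- list(term("sensor(sort(item(i1)))"),
                      term("sensor(sort(item(i2)))"))
      c(study, rep_len(queries, max(0L, n - length(study))))
    })
}

vm_config_of <- function(config, feedback_fn = NULL) {
  vm_config(seed = config$seed, threshold = config$threshold,
            delta_ltp = config$delta_ltp, delta_ltd = config$delta_ltd,
            w_min = config$w_min, w_max = config$w_max,
            max_steps_per_cycle = config$max_steps_per_cycle,
            stability_window = config$stability_window,
            feedback_fn = feedback_fn)
}

reward_rate_by_block <- function(state, n_presentations, block_size) {
  rewarded <- vapply(seq_len(n_presentations), function(i) {
    r <- if (i <= length(state$reward_log)) state$reward_log[[i]] else NULL
    !is.null(r) && isTRUE(r$rewarded)
  }, logical(1L))
  blocks <- split(rewarded, ceiling(seq_along(rewarded) / block_size))
  vapply(blocks, mean, numeric(1L))
}

compiled_model_cache <- new.env(parent = emptyenv())

compiled_model_for <- function(model_name, palette) {
  key <- paste(model_name, paste(palette, collapse = "+"))
  m <- compiled_model_cache[[key]]
  if (is.null(m)) {
    m <- compile_circuit(build_model(model_name, palette = palette))
    compiled_model_cache[[key]] <- m
  }
  m
}

#' Run a full experiment
#'
#' Builds and compiles the named model (memoized per model and palette),
#' generates its default input sequence (the fixed printed vector for the
#' NMTS replications), runs the machine, and analyzes the trace.  A correct
#' NMTS choice is a chosen button whose color differs from the sample
#' color.
#'
#' @param config an [experiment_config()].
#' @param inputs optional list of sensor vector terms overriding the
#'   default input sequence.
#' @param trace_path optional JSONL file to write the trace to.
#' @return An `experiment_result`: trace, classification, segmentation,
#'   reward rate by block, final weights and run diagnostics.
#' @export
run_experiment <- function(config, inputs = NULL, trace_path = NULL) {
  model <- compiled_model_for(config$model_name, config$palette)
  if (is.null(inputs)) inputs <- default_inputs(config)
  res <- vm_run(model, inputs, vm_config_of(config, make_feedback_fn(config)))
  sigs <- cycle_signatures(res$trace)
  seg <- segment_trace(sigs, config$stability_window)
  cls <- classify_behavior(seg)
  if (!is.null(trace_path)) trace_write_jsonl(res$trace, trace_path)
  structure(list(config = config,
                 trace = res$trace,
                 state = res$state,
                 signatures = sigs,
                 segmentation = seg,
                 classification = cls,
                 reward_rate_by_block = reward_rate_by_block(
                   res$state, length(inputs), config$block_size),
                 final_weights = weight_dump(res$state$weights),
                 diagnostics = res$state$diagnostics,
                 trace_path = trace_path),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment:", x$config$model_name, "-", x$config$n_presentations,
      "presentations, seed", x$config$seed, "\n")
  cat("Classification:", x$classification, "\n")
  if (x$segmentation$converged) {
    cat("Transient part: presentations 1..", x$segmentation$transient_end,
        "\n", sep = "")
    cat("Stable signature:",
        if (length(x$segmentation$stable_signature)) {
          paste(x$segmentation$stable_signature, collapse = ", ")
        } else {
          "(empty - no internal stimulus)"
        }, "\n")
  }
  rr <- x$reward_rate_by_block
  if (length(rr) && any(rr > 0)) {
    cat("Reward rate by block:", paste(sprintf("%.2f", rr), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Strategy-discrimination transfer experiment
#'
#' Trains an NMTS model on the standard configuration, then presents the
#' color-swapped configuration once and reports whether the probe produced
#' a correct choice, any exploratory fetch stimulus and any new plasticity
#' event.  A rule learner transfers (correct, no new learning); a
#' configural learner must start learning the new configuration.
#'
#' @param config an [experiment_config()] for `configural_nmts` or
#'   `rule_nmts`.
#' @return list with `trained` (the training result), `probe_correct`,
#'   `probe_fetch`, `probe_plasticity_events`, `probe_internal_stimuli`.
#' @export
run_transfer_experiment <- function(config) {
  stopifnot(config$model_name %in% c("configural_nmts", "rule_nmts"))
  trained <- run_experiment(config)
  state <- trained$state
  probe <- make_nmts_input(config$nmts_right, config$nmts_left,
                           config$nmts_sample, config$palette)
  n_plast <- length(state$plasticity_log)
  recs <- run_presentation_cycle(state, probe)
  acts <- cycle_events(recs, "effector_action")
  probe_correct <- FALSE
  if (length(acts)) {
    side <- term_format(term(acts[[1L]]$event)$args[[1L]])
    probe_correct <- !is.na(nmts_choice_color(probe, side)) &&
      nmts_choice_color(probe, side) != nmts_choice_color(probe, "sample")
  }
  list(trained = trained,
       probe_correct = probe_correct,
       probe_fetch = cycle_has_fetch(recs),
       probe_plasticity_events = length(state$plasticity_log) - n_plast,
       probe_internal_stimuli = length(cycle_events(recs, "internal_stimulus")))
}

demo_report <- function(res) {
  print(res)
  seg <- res$segmentation
  if (seg$converged && length(seg$stable_signature) == 1L) {
    a <- sync_anchor(res$trace, seg$n_cycles)
    cat("Sync anchor of final cycle: ", a$event, " in thread ", a$thread,
        " at local time (", a$local_time, ") on stream ", a$stream_seq,
        "\n", sep = "")
  }
  invisible(res)
}

#' Replicate the vanishing-trace experiment
#'
#' Runs the configural NMTS model on the repeatedly presented vector
#' `sensor(left([green]),right([red]),sample([red]))` and prints the
#' segmentation report: a transient part carrying fetch/excite/inhibit
#' stimuli followed by cycles void of any internal stimulus.
#'
#' @param seed machine seed.
#' @param n_presentations number of cycles (default 40).
#' @return the [run_experiment()] result, invisibly.
#' @export
demo_figure9 <- function(seed = 1L, n_presentations = 40L) {
  demo_report(run_experiment(experiment_config("configural_nmts",
                                               n_presentations = n_presentations,
                                               seed = seed)))
}

#' Replicate the persistent-trace experiment
#'
#' Runs the rule NMTS model on the same repeatedly presented vector and
#' prints the segmentation report: after the transient learning part every
#' cycle carries the recurrent single internal stimulus
#' `inhibit(match(left([green]),sample([red])))`, synchronized at thread
#' local time 3 with its supporting stream at sequence number 1.
#'
#' @inheritParams demo_figure9
#' @return the [run_experiment()] result, invisibly.
#' @export
demo_figure11 <- function(seed = 1L, n_presentations = 40L) {
  demo_report(run_experiment(experiment_config("rule_nmts",
                                               n_presentations = n_presentations,
                                               seed = seed)))
}
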