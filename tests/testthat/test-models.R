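# Behavioral endpoints of the six model circuits.

test_that("classical conditioning: weight equals the pairing count and cs alone responds iff trained", {
  m <- compile_circuit(build_model("classical"))
  for (k in 0:3) {
    inputs <- c(rep(list("sensor(cs,us)"), k), list("sensor(cs)"))
    res <- vm_run(m, inputs)
    expect_identical(weight_lookup(res$state$weights, "sense(cs)", "motor(cs)"),
                     k, label = paste("k =", k))
    probe <- res$trace[res$trace$presentation == k + 1L &
                         res$trace$event_kind == "effector_action", ]
    if (k >= 1L) {
      expect_identical(probe$event, "motor(cs)", label = paste("k =", k))
    } else {
      expect_identical(nrow(probe), 0L)
    }
  }
})

test_that("operant conditioning closes the learn route and opens exactly one action", {
  for (seed in 1:5) {
    res <- run_experiment(experiment_config("operant", n_presentations = 20L,
                                            seed = seed))
    w <- res$final_weights
    expect_lte(w[["ctrl(cue(C)) -> explore(K)"]], 0L)
    opened <- c(w[["ctrl(cue(C)) -> accept(cue(D))"]],
                w[["ctrl(cue(C)) -> reject(cue(D))"]]) > 0L
    expect_identical(sum(opened), 1L)
    ## consistent reward for accept: that is the action that opens
    expect_true(opened[1L])
    expect_identical(unname(utils::tail(res$reward_rate_by_block, 1L)), 1)
  }
})

test_that("configural learning converges to reactive cycles void of internal stimuli", {
  res <- run_experiment(experiment_config("configural_nmts",
                                          n_presentations = 30L, seed = 11L))
  expect_identical(res$classification, "reactive")
  counts <- vapply(res$signatures, function(s) length(s$stimuli), integer(1L))
  expect_identical(counts[[length(counts)]], 0L)
  ## progressive trimming: counts never increase after their maximum
  peak <- which.max(counts)
  expect_true(all(diff(counts[peak:length(counts)]) <= 0L))
  ## transient cycles carry fetch and excite/inhibit stimuli
  transient <- unlist(lapply(res$signatures[counts > 0L], `[[`, "stimuli"))
  expect_true(any(grepl("^fetch", transient)))
  expect_true(any(grepl("^excite|^inhibit", transient)))
})

test_that("rule learning settles on a persistent single-inhibit pattern with correct choices", {
  res <- run_experiment(experiment_config("rule_nmts", n_presentations = 30L,
                                          seed = 11L))
  expect_identical(res$classification, "rule_based")
  expect_identical(res$segmentation$stable_signature,
                   "inhibit(match(left([green]),sample([red])))")
  stable <- seq(res$segmentation$transient_end + 1L, 30L)
  acts <- res$trace[res$trace$event_kind == "effector_action" &
                      res$trace$presentation %in% stable, ]
  expect_identical(unique(acts$event), "press(left)")  # the non-matching button
  a <- sync_anchor(res$trace, 30L)
  expect_identical(a$thread, "try(match(left([green]),sample([red])))")
  expect_identical(a$local_time, 3L)
  expect_identical(a$stream_seq, 1L)
})

test_that("strategy discrimination: the rule transfers, the configural response does not", {
  for (seed in c(2L, 9L)) {
    rule <- run_transfer_experiment(
      experiment_config("rule_nmts", n_presentations = 20L, seed = seed))
    expect_true(rule$probe_correct)
    expect_false(rule$probe_fetch)
    expect_identical(rule$probe_plasticity_events, 0L)
    expect_identical(rule$probe_internal_stimuli, 1L)

    conf <- run_transfer_experiment(
      experiment_config("configural_nmts", n_presentations = 20L, seed = seed))
    expect_true(conf$probe_fetch)          # novel configuration: new learning
    expect_gt(conf$probe_internal_stimuli, 0L)
  }
})

test_that("win/stay-lose/shift recalls its last choice and shifts on a loss", {
  cfg <- experiment_config("win_stay_lose_shift", n_presentations = 14L,
                           seed = 4L,
                           wsls_reward_side = rep(c("left", "right"), each = 7L))
  res <- run_experiment(cfg)
  log <- res$state$reward_log
  acts <- vapply(seq_len(14L), function(i) log[[i]]$action, "")
  rew <- vapply(seq_len(14L), function(i) log[[i]]$rewarded, logical(1L))
  for (i in 2:14) {
    if (rew[i - 1L]) {
      expect_identical(acts[i], acts[i - 1L])      # win: stay
    } else {
      expect_false(acts[i] == acts[i - 1L])        # lose: shift
    }
  }
  ## the mid-run reversal costs exactly one trial
  expect_false(rew[8L])
  expect_true(all(rew[9:14]))
})

test_that("categorical sorting integrates item color and color bin from LTM", {
  res <- run_experiment(experiment_config("categorical_sort",
                                          n_presentations = 8L, seed = 1L))
  acts <- res$trace[res$trace$event_kind == "effector_action", ]
  expect_identical(sort(unique(acts$event)),
                   c("put(item(i1),bin(b1))", "put(item(i2),bin(b2))"))
  ## study-phase cycles produce no action; queries of unknown items block
  m <- compile_circuit(build_model("categorical_sort"))
  res2 <- vm_run(m, list("sensor(sort(item(i9)))"))
  expect_identical(nrow(res2$trace[res2$trace$event_kind == "effector_action", ]),
                   0L)
  expect_match(res2$state$diagnostics[[1L]], "blocked")
})
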