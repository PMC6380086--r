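# Circuit language: connector templates, validation diagnostics, builders,
# and the YAML round trip.

test_that("a two-node synapse compiles to capture/send and receive", {
  spec <- circuit_spec(
    name = "two_node",
    nodes = c("p(S)", "q(X)"),
    sensors = "p(S)",
    connectors = list(list(kind = "synapse", endpoints = c("p(S)", "q(X)"))),
    weights = list(list(p = "p(S)", q = "q(X)", w = 1L)))
  expect_identical(model_listing(compile_circuit(spec)),
                   c("p(S) @ 1 -> capture(S)",
                     "p(S) @ 2 -> send(q(X),S)",
                     "q(X) @ 1 -> receive(p(S),X)"))
})

test_that("a modulation connector spawns the coincidence-detector tree", {
  listing <- model_listing(compile_circuit(build_model("classical")))
  expect_true("sense(us) @ 2 -> fire(ltp(sense(cs),motor(X)))" %in% listing)
  expect_true("ltp(sense(cs),motor(X)) @ 1 -> join(ltp_tok(sense(cs),motor(X)))" %in% listing)
  expect_true("ltp(sense(cs),motor(X)) @ 2 -> inc_weight(sense(cs),motor(X))" %in% listing)
  ## the source merges its token before its send, as in the protocol
  cs <- grep("^sense\\(cs\\)", listing, value = TRUE)
  expect_identical(cs, c("sense(cs) @ 1 -> capture(cs)",
                         "sense(cs) @ 2 -> merge(ltp_tok(sense(cs),motor(X)))",
                         "sense(cs) @ 3 -> send(motor(X),cs)"))
})

test_that("an empty circuit compiles to an empty model", {
  m <- compile_circuit(circuit_spec(name = "void", nodes = character()))
  expect_length(m$implications, 0L)
})

test_that("validation reports dangling endpoints, arity and unknown kinds", {
  spec <- circuit_spec(
    name = "broken",
    nodes = c("p(S)", "q(X)"),
    sensors = "p(S)",
    connectors = list(
      list(kind = "synapse", endpoints = c("p(S)", "ghost(X)")),
      list(kind = "modulation_up", endpoints = c("p(S)", "q(X)")),
      list(kind = "teleport", endpoints = c("p(S)", "q(X)"))))
  d <- validate_circuit(spec)
  expect_length(d, 3L)
  expect_match(d[1L], "dangling endpoint ghost")
  expect_match(d[2L], "bad arity")
  expect_match(d[3L], "unknown kind")
  expect_error(compile_circuit(spec), "invalid circuit")
  expect_length(validate_circuit(build_model("classical")), 0L)
})

test_that("unknown opcodes in rules are rejected at compile time", {
  spec <- circuit_spec(
    name = "badop", nodes = "p(S)", sensors = "p(S)",
    rules = list(list(thread = "p(S)", clock = 1, instr = "teleport(S)")))
  expect_match(validate_circuit(spec), "unknown opcode")
  expect_error(compile_circuit(spec), "unknown opcode")
})

test_that("all six builders validate, and compilation is deterministic", {
  for (name in c("classical", "operant", "configural_nmts", "rule_nmts",
                 "win_stay_lose_shift", "categorical_sort")) {
    spec <- build_model(name)
    expect_length(validate_circuit(spec), 0L)
    l1 <- model_listing(compile_circuit(spec))
    l2 <- model_listing(compile_circuit(build_model(name)))
    expect_identical(l1, l2, label = name)
  }
})

test_that("circuit YAML round-trips to an identical compiled model", {
  for (name in c("classical", "operant", "configural_nmts", "rule_nmts",
                 "win_stay_lose_shift", "categorical_sort")) {
    spec <- build_model(name)
    path <- withr::local_tempfile(fileext = ".yaml")
    write_circuit(spec, path)
    spec2 <- read_circuit(path)
    expect_identical(model_listing(compile_circuit(spec2)),
                     model_listing(compile_circuit(spec)), label = name)
    m1 <- compile_circuit(spec)
    m2 <- compile_circuit(spec2)
    expect_identical(weight_dump(weight_table(m2$weights)),
                     weight_dump(weight_table(m1$weights)), label = name)
  }
})

test_that("the shipped circuit files compile identically to the builders", {
  dir <- system.file("extdata", "circuits", package = "fibervm")
  skip_if(dir == "", "circuit files not installed")
  for (name in c("classical", "operant", "configural_nmts", "rule_nmts",
                 "win_stay_lose_shift", "categorical_sort")) {
    shipped <- read_circuit(file.path(dir, paste0(name, ".yaml")))
    expect_identical(model_listing(compile_circuit(shipped)),
                     model_listing(compile_circuit(build_model(name))),
                     label = name)
  }
})

test_that("the operant circuit starts with the learn route open and both actions closed", {
  m <- compile_circuit(build_model("operant"))
  wt <- weight_table(m$weights)
  expect_true(weight_lookup(wt, "ctrl(cue(key))", "explore(ctrl(cue(key)))") >
                wt$threshold)
  expect_false(weight_lookup(wt, "ctrl(cue(key))", "accept(cue(key))") >
                 wt$threshold)
  expect_false(weight_lookup(wt, "ctrl(cue(key))", "reject(cue(key))") >
                 wt$threshold)
})

test_that("the configural circuit routes exploration through an internal fetch", {
  listing <- model_listing(compile_circuit(build_model("configural_nmts")))
  expect_true(any(grepl("emit\\(fetch", listing)))
})
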