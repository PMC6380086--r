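Package: fibervm
Title: Symbolic Virtual Machine for Asynchronous Neural Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A symbolic virtual machine in which concurrent threads with
    local clocks stand for neurons or neural assemblies and communicate
    through weight-gated plasticity protocols (synaptic send/receive,
    coincidence-driven long-term potentiation and depression, a short-term
    cache and an associative long-term memory). Circuits wiring sensors to
    effectors are described in a small connector language, compiled to
    virtual-code implications and executed by a deterministic
    sense-act-reflect cycle. Ships builders for six model circuits (classical
    and operant conditioning, configural and rule-based non-matching-to-sample,
    win/stay-lose/shift and categorical sorting) together with execution-trace
    analysis that segments traces into transient and persistent parts and
    classifies behavior as reactive or rule-based.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
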