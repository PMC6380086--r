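# fibervm

A symbolic virtual machine for simulating **asynchronous neural dynamics**.
Neurons or neural assemblies are modeled as concurrent *threads*, each with
its own local clock; there is no central clock. Threads are grouped into
disjoint *fibers*, and a fiber containing at least one active thread forms a
*stream* carrying a per-cycle sequence number. Synaptic plasticity is
abstracted as a set of communication protocols between threads:

| protocol        | mechanism it abstracts                              |
|-----------------|-----------------------------------------------------|
| `send`/`receive`| synaptic transmission, gated by an integer weight   |
| `join`/`merge`  | coincidence detection driving LTP/LTD (±1 on a weight) |
| `push`/`pull`   | a bounded short-term cache (STM)                    |
| `store`/`retrieve` | an associative long-term memory (LTM)            |

A *receive* proceeds only when the weight on its pathway stands strictly
above a threshold (default 0), so weight 1 is an open pathway and weight 0 a
closed one; long-term potentiation and depression increment and decrement
these integer weights, opening and closing pathways — a wiring/unwiring
process in which inhibition enables later disinhibition.

Circuits wiring sensors to effectors are written in a small description
language (nodes plus connectors: synapse, modulation, conjunction, split,
choice) and compiled to *virtual-code implications*: rules mapping a
(thread identity, local clock) pair to the instruction to execute. The
machine deduces each instruction just in time by unification (*contextual
deduction*), advances the thread's clock by one when the instruction
succeeds, and retries it when it blocks. Each input presentation runs a
deterministic **sense–act–reflect** cycle whose reflected trace records
every synchronization event: sensor captures, internal stimuli (`fetch`,
`excite`, `inhibit`) and effector actions, each paired with the thread's
local time and its supporting stream's sequence number.

The package ships six model circuits — classical conditioning, operant
conditioning, configural and rule-based non-matching-to-sample (NMTS),
win/stay–lose/shift, and categorical sorting — together with trace analysis
that segments a run into a *transient* part (cycle signatures still
changing) and a *persistent* part (a recurrent signature), classifying the
behavior as `reactive` (stable cycles void of internal stimuli) or
`rule_based` (a recurrent internal-stimulus pattern).

## Worked example

Train the rule-learning NMTS circuit on the repeatedly presented stimulus
vector `sensor(left([green]),right([red]),sample([red]))` — a green left
button, a red right button and a red sample; the rewarded choice is the
button that does *not* match the sample:

```r
library(fibervm)
demo_figure11(seed = 1)
```

```
Experiment: rule_nmts - 40 presentations, seed 1
Classification: rule_based
Transient part: presentations 1..1
Stable signature: inhibit(match(left([green]),sample([red])))
Reward rate by block: 1.00 1.00 1.00 1.00
Sync anchor of final cycle: inhibit(match(left([green]),sample([red]))) in thread try(match(left([green]),sample([red]))) at local time (3) on stream 1
```

After a short transient in which exploration (`fetch`) and reward feedback
(`excite`) open the avoid-the-match route and close the exploratory one,
every cycle repeats a single internal stimulus: the `inhibit` of the
refuted match hypothesis (green left vs. red sample), emitted by its `try`
thread at local clock 3, synchronized with stream sequence number 1 — a
persistent recurrent pattern. The configural learner on the same input
(`demo_figure9(seed = 1)`) instead converges to cycles *void of any
internal stimulus*: a purely reactive sensor-to-effector association.
Presenting the color-swapped configuration discriminates the two
strategies: the rule transfers immediately with no new plasticity, while
the configural learner must start exploring again
(`run_transfer_experiment()`).

Lower-level entry points: `build_model()` / `compile_circuit()` /
`vm_run()` for custom circuits and input sequences, `cycle_signatures()` /
`segment_trace()` / `classify_behavior()` / `sync_anchor()` for trace
analysis, `trace_write_jsonl()` for the trace format, `write_circuit()` for
the YAML circuit files (the six shipped wirings are in
`inst/extdata/circuits/`).

A thin CLI wraps the same functions:

```sh
exec/fibervm run --model rule_nmts --trials 40 --seed 1 --trace-out trace.jsonl
exec/fibervm analyze --trace trace.jsonl
exec/fibervm demo figure9
```

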