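---
title: "A symbolic virtual machine for asynchronous neural dynamics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A symbolic virtual machine for asynchronous neural dynamics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibervm)
```

## The model

`fibervm` simulates neural dynamics at the level of communicating symbolic
processes rather than membrane currents or summed activations. A *thread*
stands for a neuron or a neuron group; it owns a local clock `T` that starts
at 1 and advances by exactly one each time an instruction succeeds. There is
no global program counter: the only shared resources are the signal queue,
the merge-token pool, the plastic weight table and the two memories. Threads
are grouped into *fibers* (assemblies); a fiber holding at least one active
thread constitutes a *stream*, and streams are numbered 1, 2, ... in
activation order within each presentation cycle. A trace record is a
synchronization event — a sensor capture, an internal stimulus or an
effector action — annotated with the emitting thread, its local time, and
its stream's sequence number.

A circuit is compiled to *virtual-code implications*: ordered rules mapping
a (thread-identity pattern, clock value) pair to one instruction. At each
step the machine deduces the instruction for a thread by unifying the
implication heads, in declaration order, against the thread's current
identity and clock (contextual deduction). Because deduction is keyed only
on the identity term, anything a thread must remember between ticks has to
be carried in its identity: a receive, join, pull or retrieve that binds
variables instantiates the identity in place. This is why, for example, the
coincidence-detector threads are named `ltp(Action, Key)` — the join that
detects the coincidence binds `Key`, and the subsequent weight increment
reads it back from the identity.

### Assumptions worth stating

* **Discrete integer weights.** A pathway is open when its weight is
  strictly above the threshold (default 0); potentiation adds +1,
  depression −1, clamped to [−5, 5]. These are the smallest integers
  realizing open/closed gating with head-room for repeated pairings; no
  real-valued dynamics are modeled.
* **Cycle-local transients.** Signals, merge tokens and threads themselves
  exist only within one presentation cycle; only weights, the short-term
  cache and the long-term store persist. This keeps trials independent and
  prevents ghost coincidences across presentations.
* **Blocking as a normal outcome.** A receive whose gate is closed leaves
  the signal in the queue (a later potentiation within the same cycle may
  open the pathway); a blocked instruction is simply retried on later
  rounds.

## Scheduling and determinism

The scheduler is a cooperative round-robin: every thread active at the
start of a round attempts exactly one instruction, ordered by (fiber
activation order, spawn order); threads fired during a round join the next
one. A cycle quiesces when a full round advances nothing; if blocked
threads or pending signals remain at that point, the cycle ends with a
diagnostic rather than an error (a circular wait is a legitimate outcome of
a wiring, not a simulator fault). A per-cycle budget of instruction
attempts (`max_steps_per_cycle`, default 10,000) guards against runaway
cycles and raises an error carrying the partial trace.

The machine owns a Park–Miller linear congruential generator seeded from
the run configuration; its only consumer is the `choose` instruction
(uniform pick among currently open alternatives). R's global RNG is never
touched, and two runs with identical model, inputs and seed produce
byte-identical serialized traces. The interleaving itself is deterministic,
but the design intends the observable outcomes not to depend on it: the
test suite checks the coincidence microcircuit against an exhaustive
enumeration of scheduler interleavings, and the machine against an
independent brute-force interpreter on a family of small circuits.

## The protocol vocabulary and its parameters

Four protocol pairs abstract plasticity: `send`/`receive` (synaptic
transmission through the weight gate), `join`/`merge` (coincidence
detection driving `inc_weight`/`dec_weight`), `push`/`pull` (a bounded FIFO
short-term cache, default capacity 1 — "one's last choice"), and
`store`/`retrieve` (an append-only long-term memory with unification-based,
most-recent-first retrieval; recency is a conventional choice, the store
order itself is preserved). Defaults, all configurable through
`vm_config()` / `experiment_config()`:

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0 | strict gate: receive needs weight > threshold |
| `delta_ltp`, `delta_ltd` | +1, −1 | weight change per coincidence |
| `w_min`, `w_max` | −5, +5 | clamp range |
| `max_steps_per_cycle` | 10,000 | per-cycle attempt budget |
| `stability_window` | 5 | cycles a signature must repeat to count as persistent |

The stability window quantifies "persistent": the reference traces show
but do not count the repetition, and five consecutive identical signatures
is short enough to detect within a 40-presentation run yet long enough to
exclude alternations.

## The circuit language

`circuit_spec()` declares nodes (thread-identity patterns), connectors
drawn from a closed kind set (synapse, modulation up/down, conjunction,
split, choice), initial weights, and optionally hand-written `rules`.
Connectors compile by templates: sensors get a capture followed by one send
per outgoing connector; synapse targets get gated receives (collapsed into
one first-signal-wins receive where a choice connector covers them);
modulation gives the modulator a `fire` of the detector thread, the source
a `merge` token, and contributes the detector's `join` + weight-adjust
tree; split fans a send out.

The `rules` field exists because the figure-level wiring of the two NMTS
circuits is not recoverable from the available material and their
internal-stimulus layers (deduction-based match evaluation, exploratory
fetch/choose, feedback-driven potentiation) cannot be expressed by the six
connector kinds alone. A node that owns rules owns its whole instruction
tree; connectors to it still generate the *sender's* send. Observable trace
structure — not any particular wiring diagram — is the fidelity criterion
for these reconstructions, and the six shipped wirings are exported as
editable YAML (`inst/extdata/circuits/`).

## The six circuits and the open design choices

**Classical conditioning** is wired purely from connectors: an open
unconditioned pathway, a closed conditioned pathway, and a modulation
connector whose ltp thread joins the conditioned sensor's token and
increments the conditioned pathway. After *k* pairings the weight is
exactly *k*, and the conditioned stimulus alone triggers the reflex iff
*k* ≥ 1.

**Operant conditioning** starts with the exploratory route open
(`learn[accept(I)]` in spirit) and both actions closed. Exploration emits
an internal `fetch` that drives a random choice; rewarded choices trigger
an ltp that opens the chosen action's pathway and an ltd that closes the
exploratory gate — inhibition enabling disinhibition.

**Configural NMTS** extends the operant scheme with one *ground* pathway
triple per stimulus configuration (response links and exploration gate
keyed by the full `cfg(left,right,sample)` term). What is learned is
therefore configuration-specific by construction, which is precisely what
"configural" means here: converged cycles are void of internal stimuli, and
a color-swapped probe finds untouched gates and must explore anew.

**Rule NMTS** adds two layers: per-side `try(match(side, sample))` threads
receive the sample and evaluate the color coincidence *by deduction* — an
equal-colors implication head with a repeated variable is declared before
the generic head, so structural equality of the color terms decides the
branch and the evaluation generalizes to unseen colors without any learned
per-pair weight. The thread whose match hypothesis is refuted emits
`inhibit(match(...))` at local clock 3 (receive, evaluate, emit); the
learned avoid-route — a single *pattern-level* pathway from refuted-match
hypotheses to the corresponding button — turns that stimulus into pressing
the non-matching button. Declaring that route at pattern level (one entry,
variables for side and colors) rather than per side is what makes the rule
transfer to the mirrored configuration with no new plasticity; the
transient still needs one rewarded exploration to open it. The ltp detector
joins the probe token that only a refuted-match thread posts, so the route
can only be opened by a reward that followed a non-match choice.

One reading deserves a note: the recurrent stable stimulus is the inhibit
of the *refuted* match hypothesis (green left against the red sample), and
its emitting thread's identity appears inside the stimulus term. The
package treats `inhibit(match(X, sample))` as "this match hypothesis is
rejected", and "avoid the match" as routing that rejection to the
corresponding button.

**Reward feedback.** The simulated subject's environment computes the
reward (for NMTS: chosen color ≠ sample color) and injects it by firing
`reward(...)`/`punish(...)` threads whose emissions are ordinary internal
stimuli. For the conditioning and NMTS circuits this injection happens only
in cycles that explored (emitted a `fetch`): once behavior flows through a
learned route, reward no longer drives any internal broadcast. This is a
design choice the source material leaves open (it treats feedback as
internal without seating the evaluator), and it is required for the two
converged trace shapes — reactive cycles void of stimuli, rule cycles with
exactly the one inhibit. Win/stay–lose/shift is the exception: its
feedback fires every trial because the short-term cache must record the
last outcome.

**Win/stay–lose/shift** and **categorical sorting** are reconstructions
original to this package (the source defers their wiring elsewhere). Both
are deliberately built from nothing beyond the protocol vocabulary: the
former pulls `last(choice, outcome)` from the capacity-1 cache and branches
by deduction (stay on win, flip on loss, explore on the seeded
`last(none,none)` sentinel); the latter stores `color(item, C)` and
`category(C, bin)` facts and integrates the two retrievals to sort an item
into its bin.

## Trace analysis

Each cycle's *signature* is the ordered sequence of its internal stimuli,
compared by exact term equality after canonical variable renaming.
`segment_trace()` finds the maximal stable suffix (the final signature
repeated for at least the stability window); `classify_behavior()` maps an
empty stable signature to `reactive`, a non-empty one to `rule_based`, and
the absence of a stable suffix to `not_converged` — labels about trace
structure, nothing more. `sync_anchor()` returns the (thread, local time,
stream sequence) triple of a cycle's internal-stimulus record, the
coordinates in which the persistent pattern is reported.

## What the inputs emulate, and what they do not

The replication experiments present one fixed, noiseless stimulus vector
per cycle (green left, red right, red sample) to mirror the reference
traces; the transfer probe swaps the colors. Forty presentations with
blocks of ten for reward-rate reporting quantify the source's "after a few
trials"; with two buttons and uniform exploration the expected transient is
two to three cycles, so 40 leaves a wide margin (the test suite requires
100 of 100 seeds to reach a perfect final block, with 95 as the pass line).
Real discrimination experiments randomize configurations across trials, mix
in noise and motivation effects, and give the subject far richer sensors;
passing these tests therefore shows that the circuits realize the intended
learning dynamics under idealized inputs, not that they model any animal
quantitatively.

## Numerical and procedural choices

* Unification uses the occurs-check; terms are tiny, safety wins.
* Deduction ties break by declaration order; builders exploit this for the
  equal-colors shadowing.
* Weight lookup unifies the concrete pathway against the declared patterns;
  builders guarantee exactly one match per pathway in use, and an
  undeclared pathway is a hard wiring error, never silent.
* Stream sequence numbers restart at 1 each presentation cycle (late-cycle
  reference traces print small sequence numbers, which singles out the
  restart reading over a globally monotone counter).
* Degenerate inputs: an empty sensor vector runs an empty cycle (empty
  trace, state untouched); an input element matching no sensor is ignored;
  a retrieve with no matching fact blocks, ending the cycle with a
  diagnostic and no action.

## Problem sizes

The shipped experiments are desk-scale by design: single runs of 40
presentations take about a second; the full test suite — including the
exhaustive interleaving enumeration, the brute-force oracle comparisons and
the 200 convergence runs — completes in a few minutes on one core.

## Known limitations

* The connector vocabulary is not universal; behavior beyond the six kinds
  lives in explicit `rules`, which trades diagram-level readability for
  exactness.
* The NMTS wirings are reconstructions; only their observable trace
  structure is constrained.
* No spike timing, no real-valued weights, no OS-level parallelism:
  concurrency is simulated deterministically, which is a feature for
  reproducibility and a limitation for modeling genuine asynchrony noise.
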