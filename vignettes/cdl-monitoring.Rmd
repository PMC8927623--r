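---
title: "Contextual defeasible logic for multi-agent health monitoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextual defeasible logic for multi-agent health monitoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdlsentinel)
```

This vignette is the package's own account of its models and the design
choices behind them: what is computed, under which semantics, with which
defaults, and what the synthetic test bed does and does not show about real
monitoring data.

## 1. The inference problem

A home-monitoring system draws on several independent knowledge sources — a
smart home watching air quality and room conditions, a hospital-side system
watching a patient's vitals. Each source holds its own rules and facts, and
the sources exchange conclusions. Exchanged information can conflict: the
home may report "all clear" in the same instant the wearables report
tachycardia. A monolithic logic would simply be inconsistent; what is
needed is *skeptical, prioritized* conflict handling: conclude nothing when
evidence is genuinely balanced, follow the stated priority when one source
outranks the other, and report when the system as a whole cannot decide.
That is the role of contextual defeasible logic here.

## 2. The defeasible-logic kernel

### 2.1 Language

Propositional literals with strong negation only (`p`, `~p`); no
negation-as-failure in rule bodies, since the monitoring rules only ever
mention positive or negated observations. Rules come in three kinds:

* **strict** — `body → head`: the head is definite whenever the body is;
* **defeasible** — `body ⇒ head`: the head follows unless defeated;
* **defeater** — `body ↝ head`: can only block `~head`, never support
  `head`.

A theory adds facts (definite literals) and a superiority relation between
rules with complementary heads. The proof tags are the standard four:
`+Δ`/`−Δ` (written `+D`/`-D` in code) for the strict fragment and
`+∂`/`-∂` (`+d`/`-d`) for defeasible provability and refutability.

### 2.2 Chosen semantics

The published descriptions of CDL-style monitoring frameworks name the rule
classes but not a proof theory, and several published variants fit the same
prose. This package fixes **ambiguity-blocking defeasible logic with team
defeat** as its semantics, because that is the canonical variant in the CDL
literature: a literal attacked by an undefeated conflicting rule is simply
not concluded (ambiguity does not propagate), and an attacking rule may be
counter-defeated by *any* applicable superior rule supporting the
conclusion, not only the rule that proposed it. The choice is recorded
here as a design decision, not an inference from any single source.

Two priority mechanisms coexist and must be deterministic together. Each
rule carries an integer priority; between two conflicting rules the higher
priority wins. An explicit pair `r > s` overrides the numbers in either
direction. Equal priority with no explicit pair means neither rule defeats
the other — the skeptical tie. Because explicit pairs and numeric
priorities can in principle interleave into a cyclic *effective* defeat
relation, theory validation rejects not only cyclic explicit pairs but any
cyclic effective superiority; this preserves the property that both-sign
defeasible conclusions can only ever arise from an inconsistent strict part
(e.g. contradictory facts).

### 2.3 Evaluation strategy and termination

The engine computes all four tag sets as a **bottom-up least fixpoint**:
every inference condition is monotone in the set of already-derived tagged
conclusions (negative tags are themselves positively derived — `-Δ~q` is
evidence *for* `+∂q`), so repeated scanning until stabilization terminates
in at most `|literals| × 4` rounds and yields exactly the conclusions with
well-founded derivations. A literal whose only support cycles through
itself (`p ⇒ p`) is therefore neither provable *nor* refutable under the
corresponding negative tag — the same behaviour as a recursive prover that
fails any branch revisiting a pending goal. The test suite keeps such a
recursive, memoized prover (with an in-progress marker and taint-aware
caching) as an *independent oracle* written directly from the inference
conditions; engine and oracle are compared for exact equality on hundreds
of seeded random theories of up to 10 rules and 6 atoms.

## 3. The multi-context layer

Contexts are named theories with a preference rank (lower = more trusted;
default: declaration order — the sources give no trust order, and
deterministic tie-breaking needs one). Mapping rules (synonymous with
bridge rules here) import foreign conclusions: their bodies name
`context:literal` pairs, their head is local to the owner. Three design
choices matter:

* **Mappings are always defeasible.** Imported knowledge must be
  defeatable for prioritized conflict resolution to apply at all; a strict
  import would turn any cross-context disagreement into hard inconsistency.
* **Cycle semantics.** A distributed query carries its call history; a
  branch that would revisit a pending (context, literal) pair evaluates as
  unprovable there. If such a cut could have decided the outcome the
  answer is flagged `undefined` rather than `negative` — a total,
  terminating approximation chosen because the sources describe
  non-conclusive asynchronous communication without giving it a semantics.
* **Equilibrium.** The system is in equilibrium when every context's
  beliefs are consistent after all imports are weighed. The conflict
  report distinguishes hard contradictions (both `+∂p` and `+∂~p`, only
  possible via an inconsistent strict part) from *unresolved* atoms:
  both signs supported by applicable rules of equal standing, so that the
  skeptical engine concludes neither and the system cannot decide. The
  second class is what priority assignment repairs, and treating it as a
  loss of equilibrium is deliberate: a monitoring system that cannot
  conclude "emergency or not" has failed its purpose even though its
  belief set is formally consistent.

## 4. The agent world and the alert algorithm

One agent per sensor, in two groups: patient-care agents (vitals) and
environmental agents, with patient care outranking environment by default
(`PC_Agent` priority 2, `Env_Agent` 1). The monitoring cycle per tick:

1. every agent compares its reading to its inclusive normal range —
   boundary values are normal, because the ranges are stated as
   "between lo and hi";
2. strictly out-of-range readings send an alert message to the controller
   (the wire format mirrors the bracketed agent-simulator list layout and
   round-trips exactly);
3. the fired rule instances are screened for conflicts (complementary
   heads); conflicting instances form the conflicting-rule set, whose
   maximum under (priority, PC over Env, lexicographic rule id) acts while
   the rest of the set is suppressed; independent instances act on their
   own;
4. the acting instance's authorities are routed: medical chain
   (doctor, caretaker, next of kin) for patient-care instances, civil chain
   (fire department, emergency response unit, police department) for
   environmental ones;
5. severity comes from the danger-level calculus — one of
   patient/environment trouble detected gives H (high), both give S
   (severe) — plus per-sensor overrides (CO at or above 30 ppm is severe
   regardless);
6. the halt flag is set only by an external authority event, never by the
   system itself (the takeover decision is outside the system's scope);
   a halted world processes nothing until an explicit reboot event clears
   the flag and the pending conflict state.

The agent roster needed a decision: the source material names nine agents,
lists ten, and simulates seven. The default scenario ships the full
ten-sensor list; the seven-agent roster ships as an alternate scenario
config (`netlogo_replica.yaml`) so both are reproducible.

## 5. Synthetic sensor streams

The generator emulates the case-study signals, not physiology. Each sensor
draws per tick from a normal distribution centred on its documented typical
value (82 bpm for heart rate; midpoint of the range when no typical value
is documented) with spread equal to 10% of the range width, truncated to
the normal range by inverse-CDF sampling. Consequences: with an empty
anomaly schedule *no* reading can ever alert, across any seed — this is a
structural guarantee, not a statistical one — and every anomaly in a run is
one the schedule placed there verbatim. Streams are fully determined by
(spec, ticks, seed, schedule).

Documented ranges: heart rate 60–100 bpm, body temperature 97–99 °F, ECG
interval 0.6–1.2 s, EMG amplitude 50 μV–30 mV, EEG normal at 8 Hz and
above with 7 Hz or less abnormal in awake adults, CO 0.5–5 ppm typical and
5–15 ppm with a properly fixed gas stove (normal range = the union
0.5–15 ppm) with 30 ppm or more signalling a badly fitted stove (kept as
the severity threshold). Two caveats are carried in the docs rather than
silently corrected: the 7 Hz criterion is attributed to EMG in the source
prose but describes EEG, so it is stored on the EEG spec and flagged; and
systolic/diastolic BP, CO₂ and room temperature are named sensors without
documented thresholds, so their ranges (90–120 / 60–80 mmHg, < 1000 ppm,
18–27 °C) are ordinary clinical/building norms, marked GENERIC in the
config comments.

What the synthetic bed does **not** show: real vitals are autocorrelated,
drift with circadian rhythm and activity, and fail in sensor-specific ways
(dropout, spikes, baseline wander). Passing tests demonstrate the logic,
routing and replay machinery under the stated ranges — not detection
performance on clinical data.

## 6. Trace logic

The simulator produces exactly one finite event trace per seed, so
temporal properties are checked in the finite-trace (LTLf) style over that
recorded path rather than by branching-time model checking: `G p` holds
iff `p` holds at every tick-state (vacuously on the empty trace), `F p`
iff at some tick-state, and the two are dual. Protocol conformance pairs
every `ask(j, i, φ)` with a later (or same-tick) `tell(i, j, φ)` or a
standing tell rule of the asked agent. The danger-level table is exact:
(φ, ¬ψ) → H, (¬φ, ψ) → H, (φ, ψ) → S, (¬φ, ¬ψ) → none. Operators in the
source formalism without a coherent reading in this setting (a
next-operator used once, set-membership as disjunction, a
"humanitarian-assistance" action from an apparently different application
domain) are mapped to the authority-routing event or left unimplemented,
as documented interpretations.

## 7. Numerical and engineering choices

* **Problem sizes.** The property suites use 500 random theories (≤ 10
  rules, ≤ 6 atoms) for oracle equivalence, 300 for coherence, 1000 random
  traces for operator duality, 100 seeds for the no-alert guarantee, and
  the bundled 200-tick case study for end-to-end replay; these sizes give
  dense coverage of the small-theory space while keeping a full run
  comfortable on a single CPU.
* **Determinism.** Per-sensor stream seeds are derived from the scenario
  seed by a fixed affine map mod 2³¹; event payloads are serialized with
  full-precision JSON so a fixed seed replays byte-identically.
* **Degenerate inputs.** Empty theories, empty traces, empty candidate
  sets and halted worlds are all defined (vacuous G, false F, error on
  empty selection, no-op ticks); zero-spread sensors collapse to their
  baseline.
* **Tie-breaks.** Every ordering ends in a lexicographic id comparison so
  no selection depends on input order; permutation invariance is tested
  exhaustively for up to four candidates.

## 8. Known limitations

First-order rules, ambiguity propagation and well-founded variants are out
of scope, as are real FIPA/JADE interoperability, networked deployment and
actual notification delivery (authority contact is a logged event). The
equilibrium notion here is the practical "every context can decide"
check described above, not enumeration of equilibria over arbitrary
logics. Ontology-based modelling of the contexts is replaced by the
declarative YAML theory/mapping format throughout.
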