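# cdlsentinel

Rule-based patient and smart-home monitoring with **contextual defeasible
logic** (CDL). The package is for health-informatics researchers and
clinical-decision-support engineers who need a monitoring pipeline whose
alerting logic is *declarative*, *skeptical about conflicting evidence*, and
*auditable*: every conclusion is a tagged proof over an explicit rule base,
every run is a replayable event trace, and every inter-context disagreement
is either resolved by stated priorities or reported as a loss of
equilibrium.

## What's inside

1. **A propositional defeasible-logic engine.** Theories hold facts, strict
   rules (`body → head`), defeasible rules (`body ⇒ head`), defeaters
   (`body ↝ head`, which only block) and an acyclic superiority relation
   `r > s` over conflicting rules. The engine derives the four standard
   proof tags — `+Δ`/`−Δ` (definite provability/refutability from the
   strict part) and `+∂`/`−∂` (defeasible provability/refutability) —
   under ambiguity-blocking semantics with team defeat: a rule attacking a
   candidate conclusion `q` is overruled if *any* applicable rule supporting
   `q` is superior to it. Numeric rule priorities induce superiority (higher
   wins); explicit `r > s` pairs override the numbers.
2. **A multi-context system (MCS).** Contexts are independently-owned
   theories (a smart home, a smart hospital) linked by prioritized mapping
   (bridge) rules whose bodies reference foreign literals
   (`smart_home:co_alert`). Distributed queries resolve foreign literals
   recursively with cycle-safe semantics; `equilibrium_check()` reports
   whether every context's beliefs are consistent once all imports are
   weighed — the formal meaning of "the system can reach a decision".
3. **An agent world.** Ten sensor agents (vitals = patient-care agents,
   environment = environmental agents) observe synthetic streams; readings
   strictly outside each sensor's inclusive normal range raise
   FIPA-style alert messages to a controller, which builds the
   conflicting-rule set when several rule instances fire together, selects
   the maximum under (priority, PC over Env, rule id), routes the alert to
   the medical or civil authority chain, and honours the external halt
   flag (authority takeover) until reboot.
4. **Synthetic sensor streams** with truncated-normal baselines inside the
   documented clinical ranges (heart rate 60–100 bpm, body temperature
   97–99 °F, ECG interval 0.6–1.2 s, EMG 50 μV–30 mV, EEG ≥ 8 Hz, CO
   0.5–15 ppm with ≥ 30 ppm severe), scheduled anomalies injected verbatim,
   and a cross-context contradiction injector.
5. **A finite-trace temporal checker**: `G`/`F` operators over the event
   log, ask/tell protocol pairing, and the danger-level calculus
   (one triggering formula ⇒ H, both ⇒ S).

## Worked example

```r
library(cdlsentinel)

# conflicting evidence, resolved by superiority
th <- dfl_theory(
  facts = "abnormal_heart_rate",
  rules = dplyr::bind_rows(
    dfl_rule("r_hr",   "defeasible", "abnormal_heart_rate", "emergency",  priority = 2),
    dfl_rule("r_calm", "defeasible", character(),           "~emergency", priority = 1)))
prove(th, "emergency", "+d")
#> [1] TRUE
prove(th, "~emergency", "+d")
#> [1] FALSE

# the bundled Parkinson's case study: 10 sensor agents, 2 contexts,
# a 103 °F fever scheduled at tick 40
cfg <- load_scenario(system.file("extdata", "parkinsons_case_study.yaml",
                                 package = "cdlsentinel"))
res <- run_scenario(cfg)
res
#> <cdl_run> parkinsons_case_study (seed 7, 200 ticks): 1 alerts, exit RUNNING
#> equilibrium held at 185/185 monitored ticks
tidy(res)
#> # A tibble: 1 × 6
#>    tick source                 literal   severity route                       route_group
#>   <int> <chr>                  <chr>     <chr>    <chr>                       <chr>
#> 1    40 body_temperature_agent emergency high     doctor,caretaker,next_of_… medical
```

The one alert is the scheduled fever: the body-temperature agent detects
103 °F > 99 °F, the controller selects its rule instance over the home's
standing all-clear (patient-care priority 2 beats the import's 1), and the
medical chain — doctor, caretaker, next of kin — is alerted with severity
`high`. The authority then takes over (flag = 1 at tick 45), the system
halts, and a reboot at tick 60 resumes monitoring; the 185 monitored ticks
all remain in equilibrium. `autoplot(res)` draws every stream against its
normal band with the alert tick marked; `export_run(res, path, "jsonl")`
writes the replayable trace (byte-identical for a fixed seed).

A seven-agent roster replicating the original interactive simulation ships
as `netlogo_replica.yaml`, and a thin command-line wrapper is installed at
`system.file("cli", "cdl-sentinel.R")` with `run`, `check`, `query` and
`validate` subcommands.

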