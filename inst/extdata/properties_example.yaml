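# Example property file for `cdl-sentinel check <trace.jsonl> <properties.yaml>`.
# operators: G (kind occurs at every tick), G-none (kind occurs at no tick),
# F (kind occurs at some tick), ask_tell (every ask is answered).
- {name: continuously_monitoring, operator: G, kind: observation}
- {name: eventually_alerts, operator: F, kind: alert}
- {name: asks_answered, operator: ask_tell}
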