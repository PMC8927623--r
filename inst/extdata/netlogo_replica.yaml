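# Replica of the seven-agent simulation roster: a controller plus six
# context-aware sensor agents (BP, body temperature, heart rate, electrical
# activity = ECG interval, carbon level, room temperature). Same threshold
# semantics as the main case study, single hospital-side context.
name: netlogo_replica
seed: 11
ticks: 100
heartbeat_interval: 10

sensors: [systolic_bp, body_temperature, heart_rate, ecg_interval, co, room_temperature]

priorities:
  PC_Agent: 2
  Env_Agent: 1

contexts:
  - id: smart_hospital
    rank: 1
    theory:
      rules:
        - {id: r_sbp, kind: defeasible, body: [abnormal_systolic_bp], head: emergency, priority: 2}
        - {id: r_bt, kind: defeasible, body: [abnormal_body_temperature], head: emergency, priority: 2}
        - {id: r_hr, kind: defeasible, body: [abnormal_heart_rate], head: emergency, priority: 2}
        - {id: r_ecg, kind: defeasible, body: [abnormal_ecg_interval], head: emergency, priority: 2}
  - id: smart_home
    rank: 2
    theory:
      rules:
        - {id: h_co_alert, kind: defeasible, body: [abnormal_co], head: co_alert, priority: 1}

mappings:
  - {id: m_co_alert, owner: smart_hospital, body: ["smart_home:co_alert"],
     head: emergency, priority: 2}

schedule:
  - {tick: 30, sensor: body_temperature, value: 103}
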