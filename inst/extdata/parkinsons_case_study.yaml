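# Parkinson's-disease patient monitoring case study.
# Ten sensor agents plus a controller, split across a smart-home and a
# smart-hospital context. Normal ranges come from the documented thresholds
# (heart rate 60-100 bpm, body temperature 97-99 F, ECG interval 0.6-1.2 s,
# EMG 50 uV - 30 mV, EEG >= 8 Hz, CO 0.5-15 ppm with >= 30 ppm severe).
# Systolic/diastolic BP, CO2 and room-temperature ranges are GENERIC
# defaults (usual clinical / building norms; no documented case-study threshold). The context theories are
# reconstructions from the threshold prose: the published example-rule
# figures are not reproduced in the source text.
name: parkinsons_case_study
seed: 7
ticks: 200
heartbeat_interval: 25

priorities:
  PC_Agent: 2
  Env_Agent: 1

# The smart home exports an all-clear when CO is normal; the hospital's own
# vital-sign rules outrank that import, so an abnormal vital wins cleanly.
claims:
  - {rule_id: r_home_all_clear, sensor: co, trigger: normal, head: "~emergency",
     priority: 1, group: Env_Agent}

contexts:
  - id: smart_hospital
    rank: 1
    theory:
      rules:
        - {id: r_sbp, kind: defeasible, body: [abnormal_systolic_bp], head: emergency, priority: 2}
        - {id: r_dbp, kind: defeasible, body: [abnormal_diastolic_bp], head: emergency, priority: 2}
        - {id: r_bt, kind: defeasible, body: [abnormal_body_temperature], head: emergency, priority: 2}
        - {id: r_hr, kind: defeasible, body: [abnormal_heart_rate], head: emergency, priority: 2}
        - {id: r_eeg, kind: defeasible, body: [abnormal_eeg], head: emergency, priority: 2}
        - {id: r_ecg, kind: defeasible, body: [abnormal_ecg_interval], head: emergency, priority: 2}
        - {id: r_emg, kind: defeasible, body: [abnormal_emg], head: emergency, priority: 2}
  - id: smart_home
    rank: 2
    theory:
      rules:
        - {id: h_co_alert, kind: defeasible, body: [abnormal_co], head: co_alert, priority: 1}
        - {id: h_all_clear, kind: defeasible, body: [normal_co], head: all_clear, priority: 1}
        - {id: h_env, kind: defeasible, body: [abnormal_room_temperature], head: hazard, priority: 1}

mappings:
  - {id: m_co_alert, owner: smart_hospital, body: ["smart_home:co_alert"],
     head: emergency, priority: 2}
  - {id: m_all_clear, owner: smart_hospital, body: ["smart_home:all_clear"],
     head: "~emergency", priority: 1}

# The narrated emergency: an abnormally high body temperature at tick 40,
# after which the alerted authority takes over and later reboots the system.
schedule:
  - {tick: 40, sensor: body_temperature, value: 103}

authority_events:
  - {tick: 45, action: flag, value: 1}
  - {tick: 60, action: reboot}
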