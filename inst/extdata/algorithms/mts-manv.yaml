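# MTS-MANV - Manchester Triage System, mass-casualty module (in-hospital).
# Sieve structure: walking patients leave green at the first step; red
# findings are queried in the middle of the chain.
name: MTS-MANV
setting: in_hospital
scale: SK
root: n1
nodes:
  - id: n1
    item: walking
    label: "Able to walk?"
    on_yes: {out: "SK III"}
    on_no: {goto: n2}
  - id: n2
    item: airway_obstructed
    label: "Airway compromised?"
    on_yes: {out: "SK I"}
    on_no: {goto: n3}
  - id: n3
    item: resp_rate_gt29
    label: "Respiratory rate > 29/min?"
    on_yes: {out: "SK I"}
    on_no: {goto: n4}
  - id: n4
    item: unconscious
    label: "Unresponsive?"
    on_yes: {out: "SK I"}
    on_no: {goto: n5}
  - id: n5
    item: sbp_lt90
    label: "Shock (systolic BP < 90 mmHg)?"
    on_yes: {out: "SK I"}
    on_no: {goto: n6}
  - id: n6
    item: severe_pain
    label: "Severe pain?"
    on_yes: {out: "SK II"}
    on_no: {goto: n7}
  - id: n7
    item: open_fracture
    label: "Relevant injury pattern?"
    on_yes: {out: "SK II"}
    on_no: {out: "SK III"}
scale_map:
  "SK I": 1
  "SK II": 2
  "SK III": 3
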