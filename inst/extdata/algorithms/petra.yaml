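# PETRA - Prehospital Emergency Triage Rapid Algorithm (Jordanian-German
# civil-protection project).  Provisional encoding from the project
# descriptions: walking sieve first, apnoea tagged deceased (EX, excluded
# from the SK I-III comparison scale), then ABC and injury checks.
name: PETRA
setting: prehospital
scale: extended
provisional: true
root: n1
nodes:
  - id: n1
    item: walking
    label: "Able to walk?"
    on_yes: {out: "SK III"}
    on_no: {goto: n2}
  - id: n2
    item: breathing_present
    label: "Spontaneous breathing?"
    on_yes: {goto: n3}
    on_no: {out: "EX"}
  - id: n3
    item: airway_obstructed
    label: "Airway obstructed?"
    on_yes: {out: "SK I"}
    on_no: {goto: n4}
  - id: n4
    item: resp_rate_gt29
    label: "Respiratory rate > 29/min?"
    on_yes: {out: "SK I"}
    on_no: {goto: n5}
  - id: n5
    item: radial_pulse
    label: "Radial pulse palpable?"
    on_yes: {goto: n6}
    on_no: {out: "SK I"}
  - id: n6
    item: unconscious
    label: "Unconscious?"
    on_yes: {out: "SK I"}
    on_no: {goto: n7}
  - id: n7
    item: uncontrolled_bleeding
    label: "Uncontrolled bleeding?"
    on_yes: {out: "SK I"}
    on_no: {goto: n8}
  - id: n8
    item: pelvic_fracture
    label: "Pelvic fracture?"
    on_yes: {out: "SK II"}
    on_no: {goto: n9}
  - id: n9
    item: open_fracture
    label: "Open fracture?"
    on_yes: {out: "SK II"}
    on_no: {goto: n10}
  - id: n10
    item: burns_gt20
    label: "Burns > 20 % body surface?"
    on_yes: {out: "SK II"}
    on_no: {goto: n11}
  - id: n11
    item: severe_pain
    label: "Severe pain?"
    on_yes: {out: "SK II"}
    on_no: {out: "SK III"}
scale_map:
  "SK I": 1
  "SK II": 2
  "SK III": 3
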