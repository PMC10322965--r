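# PRIOR - Primaeres Ranking zur Initialen Orientierung im Rettungsdienst
# (prehospital).  ABC findings first (red), then injury-pattern checks
# (yellow), walking ability last: a non-walking patient without findings
# remains yellow.
name: PRIOR
setting: prehospital
scale: SK
root: n1
nodes:
  - id: n1
    item: unconscious
    label: "Unconscious / not responsive?"
    on_yes: {out: "SK I"}
    on_no: {goto: n2}
  - id: n2
    item: resp_distress
    label: "Respiratory distress?"
    on_yes: {out: "SK I"}
    on_no: {goto: n3}
  - id: n3
    item: radial_pulse
    label: "Radial pulse palpable?"
    on_yes: {goto: n4}
    on_no: {out: "SK I"}
  - id: n4
    item: uncontrolled_bleeding
    label: "Uncontrolled bleeding?"
    on_yes: {out: "SK I"}
    on_no: {goto: n5}
  - id: n5
    item: pelvic_fracture
    label: "Pelvic fracture?"
    on_yes: {out: "SK II"}
    on_no: {goto: n6}
  - id: n6
    item: open_fracture
    label: "Open fracture / major limb injury?"
    on_yes: {out: "SK II"}
    on_no: {goto: n7}
  - id: n7
    item: burns_gt20
    label: "Burns > 20 % body surface?"
    on_yes: {out: "SK II"}
    on_no: {goto: n8}
  - id: n8
    item: walking
    label: "Able to walk?"
    on_yes: {out: "SK III"}
    on_no: {out: "SK II"}
scale_map:
  "SK I": 1
  "SK II": 2
  "SK III": 3
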