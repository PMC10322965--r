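# JorD - Jordanian-German in-hospital project algorithm.  Provisional
# encoding: the original flow chart is distributed as project
# supplementary material; this transcription follows the project
# descriptions (red criteria first, including in-hospital FAST, then
# yellow injury-pattern discriminants, walking ability last).
name: JorD
setting: in_hospital
scale: SK
provisional: true
root: n1
nodes:
  - id: n1
    item: immediate_life_threat
    label: "Obvious immediate life threat?"
    on_yes: {out: "SK I"}
    on_no: {goto: n2}
  - id: n2
    item: airway_obstructed
    label: "Airway obstructed?"
    on_yes: {out: "SK I"}
    on_no: {goto: n3}
  - id: n3
    item: sbp_lt90
    label: "Systolic blood pressure < 90 mmHg?"
    on_yes: {out: "SK I"}
    on_no: {goto: n4}
  - id: n4
    item: fast
    label: "FAST: free intra-abdominal fluid?"
    on_yes: {out: "SK I"}
    on_no: {goto: n5}
  - id: n5
    item: pelvic_fracture
    label: "Pelvic fracture?"
    on_yes: {out: "SK II"}
    on_no: {goto: n6}
  - id: n6
    item: open_fracture
    label: "Open fracture?"
    on_yes: {out: "SK II"}
    on_no: {goto: n7}
  - id: n7
    item: penetrating_torso_injury
    label: "Penetrating torso injury?"
    on_yes: {out: "SK II"}
    on_no: {goto: n8}
  - id: n8
    item: burns_gt20
    label: "Burns > 20 % body surface?"
    on_yes: {out: "SK II"}
    on_no: {goto: n9}
  - id: n9
    item: spinal_injury
    label: "Suspected spinal injury?"
    on_yes: {out: "SK II"}
    on_no: {goto: n10}
  - id: n10
    item: severe_pain
    label: "Severe pain?"
    on_yes: {out: "SK II"}
    on_no: {goto: n11}
  - id: n11
    item: walking
    label: "Able to walk?"
    on_yes: {out: "SK III"}
    on_no: {out: "SK II"}
scale_map:
  "SK I": 1
  "SK II": 2
  "SK III": 3
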