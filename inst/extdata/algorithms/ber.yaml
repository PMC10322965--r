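# BER - Berlin in-hospital triage algorithm.  A block of red (immediate
# life threat) discriminants including the in-hospital FAST examination,
# followed by nine yellow discriminants, with walking ability deciding
# green at the end.  The long tail of yellow checks is the price of the
# algorithm's high SK II discrimination.
name: BER
setting: in_hospital
scale: SK
root: n1
nodes:
  - id: n1
    item: airway_obstructed
    label: "Airway obstructed?"
    on_yes: {out: "SK I"}
    on_no: {goto: n2}
  - id: n2
    item: resp_rate_gt29
    label: "Respiratory rate > 29/min?"
    on_yes: {out: "SK I"}
    on_no: {goto: n3}
  - id: n3
    item: radial_pulse
    label: "Radial pulse palpable?"
    on_yes: {goto: n4}
    on_no: {out: "SK I"}
  - id: n4
    item: sbp_lt90
    label: "Systolic blood pressure < 90 mmHg?"
    on_yes: {out: "SK I"}
    on_no: {goto: n5}
  - id: n5
    item: uncontrolled_bleeding
    label: "Uncontrolled bleeding?"
    on_yes: {out: "SK I"}
    on_no: {goto: n6}
  - id: n6
    item: unconscious
    label: "Unconscious?"
    on_yes: {out: "SK I"}
    on_no: {goto: n7}
  - id: n7
    item: fast
    label: "FAST: free intra-abdominal fluid?"
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
    item: amputation
    label: "Amputation injury?"
    on_yes: {out: "SK II"}
    on_no: {goto: n11}
  - id: n11
    item: penetrating_torso_injury
    label: "Penetrating torso injury?"
    on_yes: {out: "SK II"}
    on_no: {goto: n12}
  - id: n12
    item: burns_gt20
    label: "Burns > 20 % body surface?"
    on_yes: {out: "SK II"}
    on_no: {goto: n13}
  - id: n13
    item: spinal_injury
    label: "Suspected spinal injury?"
    on_yes: {out: "SK II"}
    on_no: {goto: n14}
  - id: n14
    item: hr_gt120
    label: "Heart rate > 120/min?"
    on_yes: {out: "SK II"}
    on_no: {goto: n15}
  - id: n15
    item: cap_refill_gt2
    label: "Capillary refill > 2 s?"
    on_yes: {out: "SK II"}
    on_no: {goto: n16}
  - id: n16
    item: severe_pain
    label: "Severe pain?"
    on_yes: {out: "SK II"}
    on_no: {goto: n17}
  - id: n17
    item: walking
    label: "Able to walk?"
    on_yes: {out: "SK III"}
    on_no: {out: "SK II"}
scale_map:
  "SK I": 1
  "SK II": 2
  "SK III": 3
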