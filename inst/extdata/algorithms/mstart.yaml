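# mSTaRT - modified Simple Triage and Rapid Treatment (prehospital).
# Walking patients are green; apnoeic patients are tagged deceased (EX,
# excluded from the SK I-III comparison scale); tachypnoea, absent radial
# pulse, uncontrolled bleeding or unresponsiveness are red; the remainder
# yellow.
name: mSTaRT
setting: prehospital
scale: extended
root: n1
nodes:
  - id: n1
    item: walking
    label: "Able to walk?"
    on_yes: {out: "SK III"}
    on_no: {goto: n2}
  - id: n2
    item: breathing_present
    label: "Spontaneous breathing (after airway opening)?"
    on_yes: {goto: n3}
    on_no: {out: "EX"}
  - id: n3
    item: resp_rate_gt29
    label: "Respiratory rate > 29/min?"
    on_yes: {out: "SK I"}
    on_no: {goto: n4}
  - id: n4
    item: radial_pulse
    label: "Radial pulse palpable?"
    on_yes: {goto: n5}
    on_no: {out: "SK I"}
  - id: n5
    item: uncontrolled_bleeding
    label: "Uncontrolled external bleeding?"
    on_yes: {out: "SK I"}
    on_no: {goto: n6}
  - id: n6
    item: unconscious
    label: "Does not follow commands?"
    on_yes: {out: "SK I"}
    on_no: {out: "SK II"}
scale_map:
  "SK I": 1
  "SK II": 2
  "SK III": 3
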