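# ESI - Emergency Severity Index (in-hospital, 5-level scale).  Level 1:
# immediate life-saving intervention needed; level 2: high-risk
# presentation; otherwise levels 3-5 by predicted resource needs.  The
# vital-sign danger-zone uprating (levels tagged danger_zone) lifts
# tachypnoeic or tachycardic patients to level 2; disable it by loading
# with disable_tags = "danger_zone".  Levels 1 and 2 map to SK I and
# SK II; levels 3-5 are pooled into SK III for the comparison scale.
name: ESI
setting: in_hospital
scale: ESI
root: n1
nodes:
  - id: n1
    item: immediate_life_threat
    label: "Immediate life-saving intervention required?"
    on_yes: {out: "ESI 1"}
    on_no: {goto: n2}
  - id: n2
    item: high_risk_presentation
    label: "High-risk situation / severe distress?"
    on_yes: {out: "ESI 2"}
    on_no: {goto: n3}
  - id: n3
    item: resp_rate_gt29
    label: "Danger zone: respiratory rate > 29/min?"
    tag: danger_zone
    on_yes: {out: "ESI 2"}
    on_no: {goto: n4}
  - id: n4
    item: hr_gt120
    label: "Danger zone: heart rate > 120/min?"
    tag: danger_zone
    on_yes: {out: "ESI 2"}
    on_no: {goto: n5}
  - id: n5
    item: esi_resources
    test: many
    label: "Many resources anticipated?"
    on_yes: {out: "ESI 3"}
    on_no: {goto: n6}
  - id: n6
    item: esi_resources
    test: at_least_one
    label: "One resource anticipated?"
    on_yes: {out: "ESI 4"}
    on_no: {out: "ESI 5"}
scale_map:
  "ESI 1": 1
  "ESI 2": 2
  "ESI 3": 3
  "ESI 4": 3
  "ESI 5": 3
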