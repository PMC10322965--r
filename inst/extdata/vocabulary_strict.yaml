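# Strict vocabulary variant: keeps the respiratory-rate > 20/min query as
# its own canonical item instead of folding it into > 29/min, for
# algorithms that genuinely branch on the lower threshold.
items:
  - walking
  - airway_obstructed
  - breathing_present
  - resp_rate_gt29
  - resp_rate_gt20
  - resp_distress
  - radial_pulse
  - cap_refill_gt2
  - hr_gt120
  - sbp_lt90
  - uncontrolled_bleeding
  - unconscious
  - fast
  - pelvic_fracture
  - open_fracture
  - amputation
  - penetrating_torso_injury
  - burns_gt20
  - spinal_injury
  - severe_pain
  - immediate_life_threat
  - high_risk_presentation
merge_map:
  unstable_pelvis: pelvic_fracture
  fast_positive: fast
  fast_negative: fast
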