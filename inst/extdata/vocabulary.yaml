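# Canonical query-item vocabulary for the coded vignette database.
# Raw columns listed under merge_map are consolidated into their canonical
# item (any-yes -> yes, else any-no -> no, else unknown).  Note that the
# respiratory-rate merge folds the > 20/min query into the > 29/min item,
# mirroring the consolidated study database; see vocabulary_strict.yaml for
# a variant keeping the lower threshold separate.
items:
  - walking
  - airway_obstructed
  - breathing_present
  - resp_rate_gt29
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
  resp_rate_gt20: resp_rate_gt29
  fast_positive: fast
  fast_negative: fast
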