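# Per-patient triage times (seconds per category, from published timing
# evaluations of the prehospital algorithms) and reference casemix
# distributions over SK I / II / III / EX.
profiles:
  PRIOR:
    sk1: 27
    sk2: 28
    sk3: 42
  mSTaRT:
    sk1: 35
    sk2: 20
    sk3: 10
casemixes:
  exercise:
    sk1: 0.15
    sk2: 0.20
    sk3: 0.60
    ex: 0.05
  field_mix:
    sk1: 0.07
    sk2: 0.19
    sk3: 0.74
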