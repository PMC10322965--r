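algorithm,category,sensitivity,specificity,ppv,npv,youden,overtriage_pct,undertriage_pct
BER,1,1.00,0.89,0.73,1.00,0.89,,0.0
ESI,1,0.80,0.89,0.70,0.94,0.69,,20.4
MTS-MANV,1,0.57,0.99,0.97,0.88,0.57,,42.9
JorD,1,1.00,0.88,0.71,1.00,0.88,,0.0
PETRA,1,0.73,0.99,0.95,0.92,0.72,,26.5
PRIOR,1,1.00,0.67,0.48,1.00,0.67,,0.0
mSTaRT,1,0.92,0.92,0.78,0.97,0.84,,8.2
BER,2,0.38,0.90,0.52,0.84,0.28,35.6,26.7
ESI,2,0.22,0.78,0.21,0.79,0.00,33.3,44.4
MTS-MANV,2,0.16,0.73,0.14,0.76,-0.11,2.2,82.2
JorD,2,0.11,0.99,0.83,0.80,0.11,40.0,48.9
PETRA,2,0.27,0.75,0.22,0.79,0.01,4.4,68.9
PRIOR,2,0.02,0.99,0.33,0.79,0.01,51.1,46.7
mSTaRT,2,0.13,0.81,0.16,0.77,-0.06,24.4,62.2
BER,3,0.84,0.87,0.89,0.82,0.72,15.5,
ESI,3,0.74,0.78,0.80,0.71,0.52,25.9,
MTS-MANV,3,0.72,0.51,0.65,0.60,0.23,27.6,
JorD,3,0.97,0.77,0.84,0.96,0.74,2.6,
PETRA,3,0.68,0.59,0.67,0.60,0.27,31.9,
PRIOR,3,0.72,0.78,0.80,0.70,0.50,27.6,
mSTaRT,3,0.72,0.67,0.73,0.66,0.39,28.4,
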