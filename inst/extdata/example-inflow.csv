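time_s,flow_m3s
0,0
0.02,1.2474701e-05
0.04,2.4404199e-05
0.06,3.5267115e-05
0.08,4.458869e-05
0.1,5.1961524e-05
0.12,5.7063391e-05
0.14,5.9671314e-05
0.16,5.9671314e-05
0.18,5.7063391e-05
0.2,5.1961524e-05
0.22,4.458869e-05
0.24,3.5267115e-05
0.26,2.4404199e-05
0.28,1.2474701e-05
0.3,0
0.32,0
0.34,0
0.36,0
0.38,0
0.4,0
0.42,0
0.44,0
0.46,0
0.48,0
0.5,0
0.52,0
0.54,0
0.56,0
0.58,0
0.6,0
0.62,0
0.64,0
0.66,0
0.68,0
0.7,0
0.72,0
0.74,0
0.76,0
0.78,0
0.8,0
0.82,0
0.84,0
0.86,0
0.88,0
0.9,0
0.92,0
0.94,0
0.96,0
0.98,0
1,0
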