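position,A,C,G,T
-3,0.35,0.40,0.15,0.10
-2,0.60,0.12,0.15,0.13
-1,0.09,0.05,0.80,0.06
+1,0.002,0.002,0.994,0.002
+2,0.002,0.002,0.002,0.994
+3,0.55,0.04,0.37,0.04
+4,0.70,0.08,0.12,0.10
+5,0.06,0.05,0.85,0.04
+6,0.12,0.10,0.18,0.60
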