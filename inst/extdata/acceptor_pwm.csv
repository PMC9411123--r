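position,A,C,G,T
-20,0.12,0.32,0.14,0.42
-19,0.12,0.32,0.14,0.42
-18,0.12,0.32,0.14,0.42
-17,0.12,0.32,0.14,0.42
-16,0.12,0.32,0.14,0.42
-15,0.12,0.32,0.14,0.42
-14,0.12,0.32,0.14,0.42
-13,0.12,0.32,0.14,0.42
-12,0.10,0.34,0.12,0.44
-11,0.10,0.34,0.12,0.44
-10,0.10,0.34,0.12,0.44
-9,0.10,0.34,0.12,0.44
-8,0.10,0.34,0.12,0.44
-7,0.10,0.34,0.12,0.44
-6,0.10,0.34,0.12,0.44
-5,0.10,0.30,0.10,0.50
-4,0.25,0.30,0.20,0.25
-3,0.10,0.65,0.05,0.20
-2,0.990,0.003,0.004,0.003
-1,0.003,0.004,0.990,0.003
+1,0.25,0.10,0.50,0.15
+2,0.25,0.20,0.30,0.25
+3,0.30,0.25,0.25,0.20
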