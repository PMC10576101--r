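# Slow-official / fast-public variant of the benchmark scenario:
# within-group dependence drags the official field (p21 > 1) while the
# public field converges faster (q21 < 1).  All other keys inherit the
# preset.

[rates]
p21 = 1.5
q21 = 0.5
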