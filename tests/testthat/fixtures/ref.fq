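@r1 first
ACGTACGT
+
IIIIIIII
@r2
ACG
+r2
JJJ
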