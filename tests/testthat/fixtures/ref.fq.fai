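r1	8	10	8	9	21
r2	3	34	3	4	42
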