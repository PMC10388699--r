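s1	15	17	10	11
s2	4	38	4	5
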