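period	count
2	76943
3	10494
4	8751
5	2237
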