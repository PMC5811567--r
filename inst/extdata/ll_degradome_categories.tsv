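category	sites
0	22
1	10
2	9
3	5
4	7
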