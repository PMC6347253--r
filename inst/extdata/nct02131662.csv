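dose,responders,total
0,1,58
0.5,18,60
1,34,61
2,33,61
4,36,60
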