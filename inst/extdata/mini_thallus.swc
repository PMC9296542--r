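# synthetic hand-written miniature thallus
# type codes: germ=1 V3=2 V3l=3 V1=4 V1l=5
1 1 0 0 0 0.008 -1
2 2 0.2 0 0 0.008 1
3 4 0.38 0.09 0 0.008 2
4 4 0.39 -0.04 0 0.008 2
5 4 -0.1 0.17 0 0.008 1
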