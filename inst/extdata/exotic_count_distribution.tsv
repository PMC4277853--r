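n_exotic_per_network	n_networks
1	13
2	7
3	1
4	3
6	1
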