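A	C	G	T
5	85	5	5
80	6	8	6
4	88	4	4
5	5	85	5
6	80	8	6
5	5	85	5
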