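A	C	G	T
3	60	2	35
2	3	90	5
4	3	3	90
2	2	94	2
1	2	95	2
2	3	93	2
88	4	4	4
85	5	5	5
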