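class_mb	n	avg_size_kb	freq
2-4	1206	2998	0.36
4-8	1053	5607	0.32
8-12	416	9737	0.12
12-16	211	13852	0.06
16-20	153	17786	0.05
20-30	162	24085	0.05
>30	131	40972	0.04
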