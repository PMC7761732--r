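class_kb	n	avg_size_kb	freq
250-500	165	451	0.11
500-750	821	617	0.56
750-1000	372	850	0.25
1000-1500	106	1141	0.07
1500-2000	5	1744	0.00
>2000	2	2071	0.00
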