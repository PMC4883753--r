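gene_id	42	52	62	72	80	88	96
envA	180.5	2.1	0.8	0.4	0.2	0.1	0.3
eclB	0.2	0.5	0.9	1.2	2.4	8.8	210.0
hkC	55.0	60.2	58.7	61.0	57.3	59.9	56.4
riseD	1.0	2.2	4.1	8.3	16.0	33.5	64.2
dimE	0.3	0.2	0.4	0.1	0.2	0.3	0.2
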