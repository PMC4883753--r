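isoform_id	gene_id	42	52	62	72	80	88	96
swA-RA	swA	42.0	3.5	2.8	2.1	1.5	1.0	0.8
swA-RB	swA	4.0	38.0	30.1	25.3	18.2	12.0	9.5
soloB-RA	soloB	10.0	11.2	9.8	10.5	10.1	9.9	10.3
stabC-RA	stabC	30.0	28.5	31.2	29.8	30.5	29.1	30.8
stabC-RB	stabC	5.0	4.8	5.2	5.1	4.9	5.0	5.3
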