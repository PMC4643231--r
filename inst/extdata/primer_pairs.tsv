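name	forward	reverse	ecoli_start	ecoli_stop
V3_U341F_534R	CCTACGGGAGGCAGCAG	ATTACCGCGGCTGCTGG	341	534
V4_515F_806R	GTGCCAGCMGCCGCGGTAA	GGACTACHVGGGTWTCTAAT	515	806
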