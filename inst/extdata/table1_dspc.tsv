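accession	F210	F290	F350	BAIT1	BAIT2	CTRL1	CTRL2
Piccolo	0	12	0	159	10	0	0
Bassoon	0	1	0	2	1	0	0
CAST2/ELKS	31	35	0	0	0	0	0
Liprin alpha2	1	2	1	0	0	0	0
CASK	0	2	0	0	0	0	0
Git1	0	24	0	0	0	0	0
Git2	0	3	0	0	0	0	0
Munc-18	9	3	0	0	0	1	0
Daam1	1	0	0	0	3	0	0
Trio	0	7	0	2	0	0	0
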