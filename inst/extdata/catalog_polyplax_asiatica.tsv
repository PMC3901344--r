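# species	minichrom_id	ordinal	gene	orientation
Polyplax_asiatica	atp8-atp6	1	atp8	+
Polyplax_asiatica	atp8-atp6	2	atp6	+
Polyplax_asiatica	E-cob-I	1	trnE	+
Polyplax_asiatica	E-cob-I	2	cob	+
Polyplax_asiatica	E-cob-I	3	trnI	+
Polyplax_asiatica	cox1-L2	1	cox1	+
Polyplax_asiatica	cox1-L2	2	trnL2	+
Polyplax_asiatica	D-Y-cox2-nad6	1	trnD	+
Polyplax_asiatica	D-Y-cox2-nad6	2	trnY	+
Polyplax_asiatica	D-Y-cox2-nad6	3	cox2	+
Polyplax_asiatica	D-Y-cox2-nad6	4	nad6	+
Polyplax_asiatica	R-nad4L-cox3-A	1	trnR	+
Polyplax_asiatica	R-nad4L-cox3-A	2	nad4L	+
Polyplax_asiatica	R-nad4L-cox3-A	3	cox3	+
Polyplax_asiatica	R-nad4L-cox3-A	4	trnA	+
Polyplax_asiatica	S1-S2-nad1-T-G-nad3-W	1	trnS1	+
Polyplax_asiatica	S1-S2-nad1-T-G-nad3-W	2	trnS2	+
Polyplax_asiatica	S1-S2-nad1-T-G-nad3-W	3	nad1	-
Polyplax_asiatica	S1-S2-nad1-T-G-nad3-W	4	trnT	-
Polyplax_asiatica	S1-S2-nad1-T-G-nad3-W	5	trnG	+
Polyplax_asiatica	S1-S2-nad1-T-G-nad3-W	6	nad3	+
Polyplax_asiatica	S1-S2-nad1-T-G-nad3-W	7	trnW	+
Polyplax_asiatica	Q-nad2-N-P	1	trnQ	+
Polyplax_asiatica	Q-nad2-N-P	2	nad2	+
Polyplax_asiatica	Q-nad2-N-P	3	trnN	+
Polyplax_asiatica	Q-nad2-N-P	4	trnP	+
Polyplax_asiatica	K-nad4-F	1	trnK	+
Polyplax_asiatica	K-nad4-F	2	nad4	+
Polyplax_asiatica	K-nad4-F	3	trnF	+
Polyplax_asiatica	H-nad5	1	trnH	+
Polyplax_asiatica	H-nad5	2	nad5	+
Polyplax_asiatica	rrnS-C	1	rrnS	+
Polyplax_asiatica	rrnS-C	2	trnC	+
Polyplax_asiatica	M-L1-rrnL-V	1	trnM	+
Polyplax_asiatica	M-L1-rrnL-V	2	trnL1	+
Polyplax_asiatica	M-L1-rrnL-V	3	rrnL	+
Polyplax_asiatica	M-L1-rrnL-V	4	trnV	+
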