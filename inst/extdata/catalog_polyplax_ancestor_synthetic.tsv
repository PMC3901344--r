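# Synthetic reconstruction: gene arrangement of the most recent common
# ancestor of the two Polyplax rat lice, assembled from the arrangements
# shared with the pig-louse/human-louse outgroups. Not a sequenced genome.
# species	minichrom_id	ordinal	gene	orientation
Polyplax_ancestor	atp8-atp6	1	atp8	+
Polyplax_ancestor	atp8-atp6	2	atp6	+
Polyplax_ancestor	E-cob-I	1	trnE	+
Polyplax_ancestor	E-cob-I	2	cob	+
Polyplax_ancestor	E-cob-I	3	trnI	+
Polyplax_ancestor	cox1-L2	1	cox1	+
Polyplax_ancestor	cox1-L2	2	trnL2	+
Polyplax_ancestor	D-Y-cox2-nad6	1	trnD	+
Polyplax_ancestor	D-Y-cox2-nad6	2	trnY	+
Polyplax_ancestor	D-Y-cox2-nad6	3	cox2	+
Polyplax_ancestor	D-Y-cox2-nad6	4	nad6	+
Polyplax_ancestor	R-nad4L-P-cox3-A	1	trnR	+
Polyplax_ancestor	R-nad4L-P-cox3-A	2	nad4L	+
Polyplax_ancestor	R-nad4L-P-cox3-A	3	trnP	+
Polyplax_ancestor	R-nad4L-P-cox3-A	4	cox3	+
Polyplax_ancestor	R-nad4L-P-cox3-A	5	trnA	+
Polyplax_ancestor	S1-S2-nad1-T-G-nad3-W	1	trnS1	+
Polyplax_ancestor	S1-S2-nad1-T-G-nad3-W	2	trnS2	+
Polyplax_ancestor	S1-S2-nad1-T-G-nad3-W	3	nad1	-
Polyplax_ancestor	S1-S2-nad1-T-G-nad3-W	4	trnT	-
Polyplax_ancestor	S1-S2-nad1-T-G-nad3-W	5	trnG	+
Polyplax_ancestor	S1-S2-nad1-T-G-nad3-W	6	nad3	+
Polyplax_ancestor	S1-S2-nad1-T-G-nad3-W	7	trnW	+
Polyplax_ancestor	Q-nad2-N	1	trnQ	+
Polyplax_ancestor	Q-nad2-N	2	nad2	+
Polyplax_ancestor	Q-nad2-N	3	trnN	+
Polyplax_ancestor	K-nad4	1	trnK	+
Polyplax_ancestor	K-nad4	2	nad4	+
Polyplax_ancestor	H-nad5-F	1	trnH	+
Polyplax_ancestor	H-nad5-F	2	nad5	+
Polyplax_ancestor	H-nad5-F	3	trnF	+
Polyplax_ancestor	rrnS-C	1	rrnS	+
Polyplax_ancestor	rrnS-C	2	trnC	+
Polyplax_ancestor	M-L1-rrnL-V	1	trnM	+
Polyplax_ancestor	M-L1-rrnL-V	2	trnL1	+
Polyplax_ancestor	M-L1-rrnL-V	3	rrnL	+
Polyplax_ancestor	M-L1-rrnL-V	4	trnV	+
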