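# species	minichrom_id	ordinal	gene	orientation
Polyplax_spinulosa	atp8-atp6	1	atp8	+
Polyplax_spinulosa	atp8-atp6	2	atp6	+
Polyplax_spinulosa	E-cob-I	1	trnE	+
Polyplax_spinulosa	E-cob-I	2	cob	+
Polyplax_spinulosa	E-cob-I	3	trnI	+
Polyplax_spinulosa	cox1-L1	1	cox1	+
Polyplax_spinulosa	cox1-L1	2	trnL1	+
Polyplax_spinulosa	T-D-Y-cox2-nad6-A	1	trnT	+
Polyplax_spinulosa	T-D-Y-cox2-nad6-A	2	trnD	+
Polyplax_spinulosa	T-D-Y-cox2-nad6-A	3	trnY	+
Polyplax_spinulosa	T-D-Y-cox2-nad6-A	4	cox2	+
Polyplax_spinulosa	T-D-Y-cox2-nad6-A	5	nad6	+
Polyplax_spinulosa	T-D-Y-cox2-nad6-A	6	trnA	+
Polyplax_spinulosa	R-nad4L-P-cox3	1	trnR	+
Polyplax_spinulosa	R-nad4L-P-cox3	2	nad4L	+
Polyplax_spinulosa	R-nad4L-P-cox3	3	trnP	+
Polyplax_spinulosa	R-nad4L-P-cox3	4	cox3	+
Polyplax_spinulosa	nad1-G-nad3-W	1	nad1	-
Polyplax_spinulosa	nad1-G-nad3-W	2	trnG	+
Polyplax_spinulosa	nad1-G-nad3-W	3	nad3	+
Polyplax_spinulosa	nad1-G-nad3-W	4	trnW	+
Polyplax_spinulosa	Q-nad2-N	1	trnQ	+
Polyplax_spinulosa	Q-nad2-N	2	nad2	+
Polyplax_spinulosa	Q-nad2-N	3	trnN	+
Polyplax_spinulosa	K-nad4	1	trnK	+
Polyplax_spinulosa	K-nad4	2	nad4	+
Polyplax_spinulosa	H-nad5-F	1	trnH	+
Polyplax_spinulosa	H-nad5-F	2	nad5	+
Polyplax_spinulosa	H-nad5-F	3	trnF	+
Polyplax_spinulosa	S1-S2-rrnS-C	1	trnS1	+
Polyplax_spinulosa	S1-S2-rrnS-C	2	trnS2	+
Polyplax_spinulosa	S1-S2-rrnS-C	3	rrnS	+
Polyplax_spinulosa	S1-S2-rrnS-C	4	trnC	+
Polyplax_spinulosa	M-L2-rrnL-V	1	trnM	+
Polyplax_spinulosa	M-L2-rrnL-V	2	trnL2	+
Polyplax_spinulosa	M-L2-rrnL-V	3	rrnL	+
Polyplax_spinulosa	M-L2-rrnL-V	4	trnV	+
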