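# Coding-region size and Illumina read support per minichromosome,
# Polyplax asiatica (Pa) and Polyplax spinulosa (Ps).
# species	minichrom_id	coding_bp	n_reads
Polyplax_asiatica	atp8-atp6	838	73276
Polyplax_asiatica	E-cob-I	1242	47008
Polyplax_asiatica	cox1-L2	1626	49653
Polyplax_asiatica	D-Y-cox2-nad6	1292	35911
Polyplax_asiatica	R-nad4L-cox3-A	1268	36763
Polyplax_asiatica	S1-S2-nad1-T-G-nad3-W	1602	21705
Polyplax_asiatica	Q-nad2-N-P	1385	24989
Polyplax_asiatica	K-nad4-F	1465	38589
Polyplax_asiatica	H-nad5	1756	39554
Polyplax_asiatica	rrnS-C	802	121142
Polyplax_asiatica	M-L1-rrnL-V	1333	57476
Polyplax_spinulosa	atp8-atp6	832	143560
Polyplax_spinulosa	E-cob-I	1228	50108
Polyplax_spinulosa	cox1-L1	1599	49675
Polyplax_spinulosa	T-D-Y-cox2-nad6-A	1399	41691
Polyplax_spinulosa	R-nad4L-P-cox3	1190	64203
Polyplax_spinulosa	nad1-G-nad3-W	1419	66380
Polyplax_spinulosa	Q-nad2-N	1134	46412
Polyplax_spinulosa	K-nad4	1331	78061
Polyplax_spinulosa	H-nad5-F	1816	44417
Polyplax_spinulosa	S1-S2-rrnS-C	904	165740
Polyplax_spinulosa	M-L2-rrnL-V	1237	96783
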