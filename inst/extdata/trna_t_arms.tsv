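# T-stem (pairs), T-loop (nt) and T-arm (nt, as printed) of the 22
# mitochondrial tRNAs of the two Polyplax rat lice.
# trna	anticodon	pa_t_stem	ps_t_stem	pa_t_loop	ps_t_loop	pa_t_arm	ps_t_arm
trnA	UGC	5	8	7	9	17	25
trnC	GCA	4	7	5	9	13	23
trnD	GUC	4	4	3	4	11	12
trnE	UUC	5	3	11	4	21	10
trnF	GAA	5	4	6	4	16	12
trnG	UCC	5	3	5	6	15	12
trnH	GUG	4	5	4	3	12	13
trnI	GAU	5	3	6	4	16	10
trnK	UUU	5	3	3	3	13	9
trnL1	UAG	5	4	4	3	14	11
trnL2	UAA	5	4	6	4	16	12
trnM	CAU	3	4	10	3	16	11
trnN	GUU	5	3	4	3	14	9
trnP	UGG	4	4	4	3	12	11
trnQ	UUG	5	5	6	6	16	16
trnR	UCG	5	3	6	4	16	10
trnS1	UCU	5	5	8	10	18	20
trnS2	UGA	5	5	6	4	16	14
trnT	UGU	3	4	5	3	11	11
trnV	UAC	5	3	9	4	19	10
trnW	UCA	6	5	8	4	20	14
trnY	GUA	3	3	4	4	10	10
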