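(((Polyplax_asiatica,Polyplax_spinulosa)Polyplax,((Pediculus_humanus,Pediculus_capitis)Pediculus,Pthirus_pubis)human_lice)rat_human_lice,(Haematopinus_suis,Haematopinus_apri)Haematopinus)root;
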