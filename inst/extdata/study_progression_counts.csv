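equation,tp,fn,fp,tn
CKDEPI_CR_2009,75,64,63,673
CKDEPI_CYS_2012,71,68,68,668
CKDEPI_CRCYS_2012,72,67,67,669
CKDEPI_CR_2021,71,68,70,666
CKDEPI_CRCYS_2021,75,64,65,671
EKFC_CR,69,70,63,673
EKFC_CYS,63,76,51,685
EKFC_CRCYS,69,70,44,692
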