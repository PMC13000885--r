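equation,criterion,agree,total
CKDEPI_CR_2009,abs3,640,875
CKDEPI_CYS_2012,abs3,662,875
CKDEPI_CRCYS_2012,abs3,688,875
CKDEPI_CR_2021,abs3,635,875
CKDEPI_CRCYS_2021,abs3,683,875
EKFC_CR,abs3,669,875
EKFC_CYS,abs3,675,875
EKFC_CRCYS,abs3,702,875
CKDEPI_CR_2009,pct5,553,875
CKDEPI_CYS_2012,pct5,573,875
CKDEPI_CRCYS_2012,pct5,609,875
CKDEPI_CR_2021,pct5,554,875
CKDEPI_CRCYS_2021,pct5,608,875
EKFC_CR,pct5,578,875
EKFC_CYS,pct5,618,875
EKFC_CRCYS,pct5,641,875
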