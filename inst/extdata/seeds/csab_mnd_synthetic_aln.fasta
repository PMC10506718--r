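>CSAB_MND_seed01
MKEFF-IFFLVVIANAERTPYTC-RW-L-E-TGCSDNGNCS-EIGCV--GSEIG-VLKCSVTQPCG-QC-ALPDDA-CIQAYVRYGG
>CSAB_MND_seed02
MRPPL-LLLVIFIAQAERFPYRC-SW--SE-KGCSNNNGCGTEIGCILWSPEIG-VLECSFTQGCQGQC-ALP-DA-CIPAQVGLDG
>CSAB_MND_seed03
MKN---IFFLVFFANAERFPYRC-RWLLQE-RGCSN-NGCSEISGCL-GSSEIG-VLKCSFTQPCG-QCAALP-DA-CIAAQIRMDG
>CSAB_MND_seed04
MKNQF-VLLLLLLAQAERFPYRC-RW-LQE-TGCSN-NGCSIEIGCL-GSPEIGIVLKCSYTQ-CG-QC-ALP-DA-CIPAQVRLDG
>CSAB_MND_seed05
MK----VVLLLIIASAERFPYRC-RW-LQESKGCS--NGCL-EISCL-GSPEIG-VLKCTF-QPCGRQC-ALP-DA-CIPAQVRYDG
>CSAB_MND_seed06
MRD-L-LFILILIANAERFPLRCWRW-LQE-KGCSIR--CDGEIGCL--NPEIG-VIKCSFT-PCG-QC-ALP-DADCIPVEVRYDG
>CSAB_MND_seed07
MRN---VVVVFLVAQAERYPYRC-RW-LQE-KGCSNSNGCS-EI-CL--SPEIG-VLKC-FAQGCGGQC-AL--NA-CILAQVRFDG
>CSAB_MND_seed08
MKENLVLLIIFFLAQAERFTYQC-RW-RQE-KGCSNTSGCSEIEGCL--SPEAG-VLKCSFTQPCG-QC-AEP-DP-CIPAQFSYDG
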