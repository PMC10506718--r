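>CSAB_DROSOMYCIN_seed01
MKV---VLVILVFASAALHIKCVTDIVNCVRLIL-RVN-EHSRAQCFLN-ATAFCVGEGYGADCSVS-TLSP-NVCQC-GE--CKHEIGMVKG
>CSAB_DROSOMYCIN_seed02
MKN-VIIFIVFLIANAALHLKC-TDIVNC-KLML-RVN-EHN-TQC-LN--TFFCGGEVGGEYCSIS-TISVLNVCQC-GE-TCKHEIGMWEG
>CSAB_DROSOMYCIN_seed03
MKN---IFFVLIFANAALHLKC--DIVNC-RLIL-RVN-SHS-TQC-LN-ATFFCGGEV--GYCSVS-TLFL-N-CQCQGE-TCKHEIGMSEG
>CSAB_DROSOMYCIN_seed04
MRV--FLVFVIFVAQAALGLKC-TDIVNC-RLIL-RVNLEHSNTQC-LNLPTFFCGNEV-TNYCSVSTTLLL-NLCQC-GE-TCKHEIGMVEG
>CSAB_DROSOMYCIN_seed05
MKEDLVFIIIILLAQAALHLKC-ADTM-C-RLIL-RVN-WHSRTQC-LN-STFFCGGAV-GNYCSFS-TLSL-NVCQC-GE-TCKHEIGMGRG
>CSAB_DROSOMYCIN_seed06
MKE--EIVIFIVLASAALFLKC-TDIVAC-RLDLNRVN-EHSRTQC-LN-AT-FCGGDVVGNHCSVS-PLSLNSVCQC-GESTCKHEIGMVDG
>CSAB_DROSOMYCIN_seed07
MRE-PLIILIFFFASAALYLKC-TDIVNC-RLII-RVN-HHS-RQC-LN-ATFFCGGEEIGNYCSVT-TLSL--VCQC-G--TCKHEIGMVEG
>CSAB_DROSOMYCIN_seed08
MRI---FIIVLFIASAALHLKC-NDIVNC-RLIL-RDNEEHSRTQC-LL-AT-FCGGEV-GGYCSVSVTLSL-NVCQC-GEGTCKHEIGMVEG
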